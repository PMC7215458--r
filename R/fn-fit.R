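#' @title Slope-uncertainty and power-law fits for F-N series
#' @description
#' The F-N curve of a set of fatal accidents is, on log-log axes, roughly a
#' straight line lgF = -a lgN + lgC. Rather than committing to one precise
#' slope, the uncertainty of -a is modelled by fitting (i) a normal
#' distribution to the per-group slopes, (ii) an adjusted normal density
#' f(x) = B + D / (sigma sqrt(pi/2)) exp(-2 (x - mu)^2 / sigma^2) with
#' offset and amplitude parameters B and D, and (iii) a power law
#' F = C N^(-a) fitted to the curve itself. Model choice is by R^2 and
#' RMSE, and the retained fit yields a 95% confidence band of F-N lines.
#' @name fn_fit
NULL

drop_na_slopes <- function(slopes) slopes[!is.na(slopes)]

#' Histogram bin breaks for a slope sample
#'
#' Equal-width breaks spanning the sample range. `bins` may be `"sturges"`
#' (the default rule), an integer bin count, or an explicit numeric break
#' vector (returned as-is).
#' @keywords internal
slope_breaks <- function(slopes, bins = "sturges") {
  if (is.numeric(bins) && length(bins) > 1) return(bins)
  k <- if (identical(bins, "sturges")) grDevices::nclass.Sturges(slopes)
       else as.integer(bins)
  if (is.na(k) || k < 1) stop("invalid binning rule")
  r <- range(slopes)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
  seq(r[1], r[2], length.out = k + 1)
}

#' R-squared and root-mean-square error of a fit
#'
#' `r2 = 1 - SSE/SST` and the degree-of-freedom adjusted
#' `rmse = sqrt(SSE / (n - n_params))`.
#'
#' @param observed,predicted Equal-length numeric vectors, longer than
#'   `n_params`.
#' @param n_params Number of fitted parameters consumed by the model.
#' @return A list with elements `r2` and `rmse`.
#' @export
goodness_of_fit <- function(observed, predicted, n_params) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) <= n_params) stop("need more points than parameters")
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("observed values have zero variance")
  list(r2 = 1 - sse / sst, rmse = sqrt(sse / (length(observed) - n_params)))
}

#' Goodness of fit of a density against a slope histogram
#'
#' Bins the slope sample, evaluates the fitted density at the bin centers,
#' and compares it with the observed bin densities via [goodness_of_fit()].
#' Published histogram-space metrics depend on the (usually unstated)
#' binning, so the binning rule is an explicit argument.
#'
#' @param slopes Per-group slopes (NAs dropped).
#' @param density_fun Function of x returning the fitted density.
#' @param bins Binning rule passed to the histogram (see [slope_breaks]).
#' @param n_params Parameters consumed by the density fit (2 for normal,
#'   4 for the adjusted normal).
#' @return A list with `r2` and `rmse` (histogram-density space).
#' @export
goodness_of_fit_histogram <- function(slopes, density_fun, bins = "sturges",
                                      n_params = 2) {
  slopes <- drop_na_slopes(slopes)
  if (length(slopes) < 4) stop("need at least 4 slopes")
  h <- graphics::hist(slopes, breaks = slope_breaks(slopes, bins), plot = FALSE)
  goodness_of_fit(h$density, density_fun(h$mids), n_params)
}

new_slope_dist_fit <- function(family, mu, sigma, interval, r2, rmse,
                               B = NULL, D = NULL, n_slopes = NA) {
  structure(list(family = family, mu = mu, sigma = sigma, B = B, D = D,
                 interval_95 = interval, r2 = r2, rmse = rmse,
                 n_slopes = n_slopes),
            class = "slope_dist_fit")
}

#' Normal fit of the per-group slope distribution
#'
#' The slope location mu is the arithmetic mean and sigma the sample
#' standard deviation (n - 1 denominator) of the defined per-group slopes.
#' `interval_95 = mu +/- 1.96 sigma` is a population dispersion interval
#' (the plausible range of the slope itself), not a standard-error
#' confidence interval for mu; downstream fatality-ratio bounds use these
#' endpoints. Goodness of fit is measured in histogram-density space.
#'
#' @param slopes Per-group slopes (NAs, e.g. the N = 1 group, dropped).
#' @param bins Histogram binning rule for the fit metrics.
#' @return A `slope_dist_fit` with family `"normal"`.
#' @export
fit_normal <- function(slopes, bins = "sturges") {
  slopes <- drop_na_slopes(slopes)
  if (length(slopes) < 2) stop("need at least 2 defined slopes")
  mu <- mean(slopes)
  sigma <- stats::sd(slopes)
  gof <- if (length(slopes) >= 4 && sigma > 0)
    goodness_of_fit_histogram(slopes, function(x) stats::dnorm(x, mu, sigma),
                              bins, n_params = 2)
  else list(r2 = NA_real_, rmse = NA_real_)
  new_slope_dist_fit("normal", mu, sigma,
                     c(mu - 1.96 * sigma, mu + 1.96 * sigma),
                     gof$r2, gof$rmse, n_slopes = length(slopes))
}

#' Adjusted-normal fit of the per-group slope distribution
#'
#' Least-squares fit of
#' `f(x) = B + D / (sigma sqrt(pi/2)) exp(-2 (x - mu)^2 / sigma^2)`
#' to the histogram densities of the slopes; B (baseline offset) and D
#' (amplitude) are adjusting parameters. The sigma of this
#' parameterisation is not the normal-density standard deviation (the
#' exponent uses 2/sigma^2 rather than 1/(2 sigma^2)). `interval_95` is
#' the t-based confidence interval of mu from the curve fit.
#'
#' @inheritParams fit_normal
#' @return A `slope_dist_fit` with family `"improved_normal"` and fields
#'   `B` and `D`.
#' @export
fit_improved_normal <- function(slopes, bins = "sturges") {
  slopes <- drop_na_slopes(slopes)
  if (length(slopes) < 4) stop("need at least 4 defined slopes")
  h <- graphics::hist(slopes, breaks = slope_breaks(slopes, bins), plot = FALSE)
  x <- h$mids
  d <- h$density
  start <- list(B = 0, D = max(d) * 2 * stats::sd(slopes) * sqrt(pi / 2),
                mu = mean(slopes), sigma = 2 * stats::sd(slopes))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      d ~ B + D / (sigma * sqrt(pi / 2)) * exp(-2 * (x - mu)^2 / sigma^2),
      start = start, control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("adjusted-normal fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  mu <- unname(cf["mu"]); sigma <- abs(unname(cf["sigma"]))
  se_mu <- summary(fit)$coefficients["mu", "Std. Error"]
  tq <- stats::qt(0.975, df = max(length(d) - 4, 1))
  gof <- goodness_of_fit(d, as.numeric(stats::fitted(fit)),
                         n_params = min(4, length(d) - 1))
  new_slope_dist_fit("improved_normal", mu, sigma,
                     c(mu - tq * se_mu, mu + tq * se_mu),
                     gof$r2, gof$rmse,
                     B = unname(cf["B"]), D = unname(cf["D"]),
                     n_slopes = length(slopes))
}

new_powerlaw_fit <- function(a_hat, C_hat, a_int, C_int, r2, rmse, fit_space, n) {
  structure(list(a_hat = a_hat, C_hat = C_hat,
                 a_interval_95 = a_int, C_interval_95 = C_int,
                 r2 = r2, rmse = rmse, fit_space = fit_space, n_points = n),
            class = "powerlaw_fit")
}

#' Power-law fit of an F-N series in log-log space
#'
#' Ordinary least squares of lgF on lgN over all groups, including the
#' (0, 0) point of the N = 1 group. 95% intervals use the t quantile with
#' n - 2 degrees of freedom; R^2 and RMSE are in log space.
#'
#' @param series An `fn_series` (at least 3 groups for interval estimates;
#'   a 2-group series is fitted exactly, with zero-width intervals and an
#'   undefined RMSE).
#' @return A `powerlaw_fit` with `fit_space = "loglog_ols"`. `a_hat` is the
#'   slope magnitude, `C_hat = 10^intercept`.
#' @export
fit_powerlaw_loglog <- function(series) {
  stopifnot(inherits(series, "fn_series"))
  if (nrow(series) < 2) stop("need at least 2 groups")
  if (length(unique(series$lgN)) < 2) stop("degenerate series: all lgN equal")
  fit <- stats::lm(lgF ~ lgN, data = series)
  cf <- stats::coef(fit)
  n <- nrow(series)
  if (n == 2) {
    # exactly determined line: no residual degrees of freedom
    return(new_powerlaw_fit(
      a_hat = -unname(cf["lgN"]), C_hat = 10^unname(cf["(Intercept)"]),
      a_int = rep(-unname(cf["lgN"]), 2), C_int = rep(10^unname(cf["(Intercept)"]), 2),
      r2 = 1, rmse = NA_real_, fit_space = "loglog_ols", n = n))
  }
  sm <- suppressWarnings(summary(fit))  # zero-residual fits warn harmlessly
  se <- sm$coefficients[, "Std. Error"]
  tq <- stats::qt(0.975, df = n - 2)
  slope_int <- cf["lgN"] + c(-1, 1) * tq * se["lgN"]
  icpt_int <- cf["(Intercept)"] + c(-1, 1) * tq * se["(Intercept)"]
  pred <- stats::fitted(fit)
  gof <- goodness_of_fit(series$lgF, as.numeric(pred), n_params = 2)
  new_powerlaw_fit(a_hat = -unname(cf["lgN"]), C_hat = 10^unname(cf["(Intercept)"]),
                   a_int = sort(-slope_int), C_int = 10^icpt_int,
                   r2 = gof$r2, rmse = gof$rmse,
                   fit_space = "loglog_ols", n = n)
}

#' Power-law fit of an F-N series in linear frequency space
#'
#' Unweighted nonlinear least squares of F = C N^(-a) over all groups
#' (starting values from [fit_powerlaw_loglog()]). R^2 and the
#' degree-of-freedom adjusted RMSE (`sqrt(SSE/(n-2))`) are computed on the
#' F values; 95% intervals come from Jacobian linearization with the
#' t(n - 2) quantile. This is the fit space whose metrics match published
#' curve-fitting toolbox output for cumulative-frequency series.
#'
#' @param series An `fn_series` (at least 3 groups).
#' @return A `powerlaw_fit` with `fit_space = "linear_nls"`.
#' @export
fit_powerlaw_linear <- function(series) {
  stopifnot(inherits(series, "fn_series"))
  if (nrow(series) < 3) stop("need at least 3 groups")
  start_fit <- fit_powerlaw_loglog(series)
  df <- data.frame(N = series$n_deaths, F = series$F)
  fit <- tryCatch(
    minpack.lm::nlsLM(F ~ C * N^(-a), data = df,
                      start = list(C = start_fit$C_hat, a = start_fit$a_hat),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("power-law fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  n <- nrow(df)
  se <- summary(fit)$coefficients[, "Std. Error"]
  tq <- stats::qt(0.975, df = n - 2)
  gof <- goodness_of_fit(df$F, as.numeric(stats::fitted(fit)), n_params = 2)
  new_powerlaw_fit(a_hat = unname(cf["a"]), C_hat = unname(cf["C"]),
                   a_int = unname(cf["a"]) + c(-1, 1) * tq * se["a"],
                   C_int = unname(cf["C"]) + c(-1, 1) * tq * se["C"],
                   r2 = gof$r2, rmse = gof$rmse,
                   fit_space = "linear_nls", n = n)
}

#' @export
print.slope_dist_fit <- function(x, ...) {
  cat(sprintf("<slope_dist_fit: %s>\n  mu = %.4f, sigma = %.4f\n",
              x$family, x$mu, x$sigma))
  if (!is.null(x$B))
    cat(sprintf("  B = %.4f, D = %.4f\n", x$B, x$D))
  cat(sprintf("  95%% interval for the slope location: (%.4f, %.4f)\n",
              x$interval_95[1], x$interval_95[2]))
  cat(sprintf("  histogram-space R^2 = %.4f, RMSE = %.4f\n", x$r2, x$rmse))
  invisible(x)
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit: %s> F = C * N^(-a)\n", x$fit_space))
  cat(sprintf("  a = %.4f  95%% CI (%.4f, %.4f)\n",
              x$a_hat, x$a_interval_95[1], x$a_interval_95[2]))
  cat(sprintf("  C = %.4f  95%% CI (%.4f, %.4f)\n",
              x$C_hat, x$C_interval_95[1], x$C_interval_95[2]))
  cat(sprintf("  R^2 = %.4f, RMSE = %.4f (%d points)\n", x$r2, x$rmse, x$n_points))
  invisible(x)
}

#' Rank fitted models by goodness of fit
#'
#' Orders fits by descending R^2, breaking ties by ascending RMSE
#' (stable with respect to input order).
#'
#' @param fits A named list of fit objects, each carrying `r2` and `rmse`.
#' @return The list reordered best-first, with a `ranking` attribute
#'   (data frame of model, r2, rmse).
#' @export
select_model <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fits to rank")
  r2 <- vapply(fits, function(f) f$r2, numeric(1))
  rmse <- vapply(fits, function(f) f$rmse, numeric(1))
  ord <- order(-r2, rmse)
  out <- fits[ord]
  attr(out, "ranking") <- data.frame(
    model = if (!is.null(names(fits))) names(fits)[ord] else as.character(ord),
    r2 = r2[ord], rmse = rmse[ord], row.names = NULL)
  out
}

#' 95% confidence band of F-N lines
#'
#' Builds the central, lower and upper F-N lines from a fitted model. The
#' lower (optimistic) edge pairs the steepest slope with the smallest C;
#' the upper (pessimistic) edge pairs the shallowest slope with the
#' largest C, so the band nests the central line for all N >= 1. For a
#' slope-distribution fit the lines pass through (lgN, lgF) = (0, 0),
#' i.e. C = 1.
#'
#' @param fit A `powerlaw_fit` or `slope_dist_fit`.
#' @param series The `fn_series` the fit was built from (kept for the
#'   band's N support).
#' @return An object of class `fn_band` with elements `central`, `lower`,
#'   `upper` (each a list with `a` and `C`), `fit` and `series`.
#' @export
fn_band <- function(fit, series) {
  stopifnot(inherits(series, "fn_series"))
  if (inherits(fit, "powerlaw_fit")) {
    central <- list(a = fit$a_hat, C = fit$C_hat)
    lower <- list(a = max(fit$a_interval_95), C = min(fit$C_interval_95))
    upper <- list(a = min(fit$a_interval_95), C = max(fit$C_interval_95))
  } else if (inherits(fit, "slope_dist_fit")) {
    central <- list(a = -fit$mu, C = 1)
    lower <- list(a = -min(fit$interval_95), C = 1)
    upper <- list(a = -max(fit$interval_95), C = 1)
  } else stop("unsupported fit object")
  structure(list(central = central, lower = lower, upper = upper,
                 fit = fit, series = series),
            class = "fn_band")
}

#' Evaluate the edges of an F-N band
#'
#' @param band An `fn_band`.
#' @param N Fatality counts (>= 1) at which to evaluate.
#' @return A data frame with `N`, `lower`, `central`, `upper` frequencies.
#' @export
fn_band_eval <- function(band, N) {
  stopifnot(inherits(band, "fn_band"), all(N >= 1))
  line <- function(l) l$C * N^(-l$a)
  data.frame(N = N, lower = line(band$lower), central = line(band$central),
             upper = line(band$upper))
}

#' @export
print.fn_band <- function(x, ...) {
  cat("<fn_band> lgF = -a lgN + lgC\n")
  for (edge in c("lower", "central", "upper"))
    cat(sprintf("  %-8s a = %.4f, C = %.4f\n", edge, x[[edge]]$a, x[[edge]]$C))
  invisible(x)
}

#' Fatality-frequency ratio implied by a power-law slope
#'
#' For a curve with slope magnitude a, the ratio of the frequency of n1 or
#' more deaths to that of n2 or more deaths is (n2/n1)^a. Evaluating at
#' the slope-interval endpoints bounds the ratio under slope uncertainty.
#'
#' @param slope_magnitude Positive slope magnitude a.
#' @param n1,n2 Fatality counts with `n2 > n1 >= 1`.
#' @return The ratio F(>= n1) / F(>= n2).
#' @examples
#' fatality_ratio(1.1631, 10, 100)  # 14.56
#' fatality_ratio(1.5217, 10, 100)  # 33.25
#' @export
fatality_ratio <- function(slope_magnitude, n1, n2) {
  stopifnot(slope_magnitude > 0, n1 >= 1, n2 > n1)
  (n2 / n1)^slope_magnitude
}
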