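#' Plot an F-N band with ALARP criterion lines
#'
#' Log-log plot of the observed series, the central/lower/upper band
#' lines, and the tolerable and acceptable limit lines with the three
#' risk zones shaded.
#'
#' @param x An `fn_band`.
#' @param lines ALARP lines (default [default_lines()]); NULL to omit.
#' @param N_max Right edge of the N axis (defaults to the series maximum).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fn_band <- function(x, lines = default_lines(), N_max = NULL, ...) {
  series <- x$series
  if (is.null(N_max)) N_max <- max(series$n_deaths)
  Ng <- exp(seq(log(1), log(N_max), length.out = 200))
  ev <- fn_band_eval(x, Ng)
  ylim <- range(c(ev$lower, ev$upper, series$F,
                  if (!is.null(lines)) line_F(lines$acceptable, N_max)))
  graphics::plot(series$n_deaths, series$F, log = "xy", xlab = "N (deaths)",
                 ylab = "F (cumulative frequency of >= N deaths)",
                 ylim = ylim, pch = 16, ...)
  if (!is.null(lines)) {
    tol <- line_F(lines$tolerable, Ng)
    acc <- line_F(lines$acceptable, Ng)
    graphics::polygon(c(Ng, rev(Ng)), c(tol, rep(max(ylim) * 10, length(Ng))),
                      col = grDevices::adjustcolor("red", 0.08), border = NA)
    graphics::polygon(c(Ng, rev(Ng)), c(acc, rev(tol)),
                      col = grDevices::adjustcolor("orange", 0.08), border = NA)
    graphics::polygon(c(Ng, rev(Ng)), c(rep(min(ylim) / 10, length(Ng)), rev(acc)),
                      col = grDevices::adjustcolor("green", 0.08), border = NA)
    graphics::lines(Ng, tol, lty = 2, col = "red")
    graphics::lines(Ng, acc, lty = 2, col = "darkgreen")
  }
  graphics::lines(Ng, ev$central, lwd = 2)
  graphics::lines(Ng, ev$lower, lty = 3)
  graphics::lines(Ng, ev$upper, lty = 3)
  graphics::legend("bottomleft", bty = "n", lwd = c(2, 1, NA), lty = c(1, 3, NA),
                   pch = c(NA, NA, 16),
                   legend = c("central fit", "95% band", "observed"))
  invisible(x)
}

#' Plot the SSE-vs-k elbow curve
#'
#' @param sse A data frame from [elbow_sse()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_elbow <- function(sse, ...) {
  graphics::plot(sse$k, sse$sse, type = "b", pch = 16, xlab = "k",
                 ylab = "within-cluster SSE", ...)
  cand <- attr(sse, "elbow_candidates")
  if (!is.null(cand))
    graphics::abline(v = cand, lty = 3, col = "grey50")
  invisible(sse)
}
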