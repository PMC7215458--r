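#' @title F-N series construction
#' @description
#' An F-N series relates the number of fatalities N to the cumulative
#' frequency F of accidents with N or more fatalities:
#' \deqn{F_j = \frac{\sum_{i \ge j} n_i}{\sum_i n_i}}
#' where \eqn{n_i} is the number of accidents in fatality group i. On
#' log-log axes the series is summarised by per-group slopes
#' \eqn{-a_i = \lg F_i / \lg N_i}, undefined for the N = 1 group where
#' \eqn{\lg N = 0}.
#' @name fn_series
NULL

#' Group fatal accidents by death toll
#'
#' @param deaths Vector of per-accident death counts, all at least 1.
#'   Zero-death accidents must be filtered out by the caller: the F-N
#'   construction concerns fatal accidents only.
#' @return A data frame with `n_deaths` (strictly increasing) and
#'   `n_accidents`; the counts sum to `length(deaths)`.
#' @export
group_fatalities <- function(deaths) {
  if (length(deaths) == 0) stop("no fatal accidents supplied")
  if (any(is.na(deaths)) || any(deaths < 1) || any(deaths != floor(deaths)))
    stop("death counts must be integers >= 1")
  tab <- table(deaths)
  data.frame(n_deaths = as.integer(names(tab)), n_accidents = as.integer(tab))
}

#' Cumulative F-N series from fatality groups
#'
#' Computes the cumulative frequency F of N or more fatalities per group,
#' base-10 log pairs, and per-group slopes lgF/lgN (NA for the smallest
#' group when its N is 1).
#'
#' @param groups A data frame with columns `n_deaths` and `n_accidents`
#'   (as from [group_fatalities()]); rows may be in any order but
#'   `n_deaths` must be distinct.
#' @return An object of class `fn_series`: a data frame with columns
#'   `n_deaths`, `n_accidents`, `F`, `lgN`, `lgF`, `slope`, and attribute
#'   `total_accidents`.
#' @export
cumulative_frequency <- function(groups) {
  stopifnot(is.data.frame(groups),
            all(c("n_deaths", "n_accidents") %in% names(groups)))
  if (anyDuplicated(groups$n_deaths)) stop("duplicate n_deaths groups")
  if (any(groups$n_accidents < 1)) stop("each group needs at least one accident")
  if (any(groups$n_deaths < 1)) stop("n_deaths must be >= 1")
  groups <- groups[order(groups$n_deaths), , drop = FALSE]
  total <- sum(groups$n_accidents)
  F <- rev(cumsum(rev(groups$n_accidents))) / total
  lgN <- log10(groups$n_deaths)
  lgF <- log10(F)
  slope <- ifelse(lgN > 0, lgF / lgN, NA_real_)
  out <- data.frame(n_deaths = as.integer(groups$n_deaths),
                    n_accidents = as.integer(groups$n_accidents),
                    F = F, lgN = lgN, lgF = lgF, slope = slope)
  structure(out, class = c("fn_series", "data.frame"), total_accidents = total)
}

#' F-N series from raw death counts
#'
#' Convenience composition of [group_fatalities()] and
#' [cumulative_frequency()].
#'
#' @inheritParams group_fatalities
#' @return An `fn_series` object.
#' @export
fn_series_from_deaths <- function(deaths) {
  cumulative_frequency(group_fatalities(deaths))
}

#' F-N series from a pre-grouped (N, count) table
#'
#' Accepts the two-column dialect of published fatality-group tables. Rows
#' may be in any order; duplicate N values are an error.
#'
#' @param rows A data frame with columns `n_deaths` and `n_accidents`, or a
#'   path to a delimited file with those columns.
#' @return An `fn_series` object.
#' @export
fn_series_from_table <- function(rows) {
  if (is.character(rows)) rows <- utils::read.csv(rows)
  cumulative_frequency(rows[c("n_deaths", "n_accidents")])
}

#' Per-point log-log slopes
#'
#' The slope of fatality group i is lgF_i / lgN_i; it is undefined (NA)
#' where lgN is 0, i.e. for the N = 1 group.
#'
#' @param lgN,lgF Equal-length vectors of base-10 logs (lgN non-negative).
#' @return Numeric vector of slopes with NA where lgN is 0.
#' @export
pointwise_slopes <- function(lgN, lgF) {
  if (length(lgN) != length(lgF)) stop("lgN and lgF differ in length")
  if (any(lgN < 0)) stop("lgN must be non-negative")
  ifelse(lgN > 0, lgF / lgN, NA_real_)
}

#' @export
print.fn_series <- function(x, digits = 3, ...) {
  cat(sprintf("<fn_series> %d fatality groups, %d accidents\n",
              nrow(x), attr(x, "total_accidents")))
  df <- as.data.frame(x)
  df$F <- round(df$F, digits)
  df$lgN <- round(df$lgN, digits)
  df$lgF <- round(df$lgF, digits)
  df$slope <- round(df$slope, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' The 2004-2018 China HTA fatality-group series
#'
#' The packaged 19-group fatality series of fatal hazmat transportation
#' accidents in China, 2004-2018, as published (N, group count, cumulative
#' frequency F, base-10 logs, per-group slope). The published cumulative
#' frequencies are not exactly the count ratios (e.g. F at N >= 2 is
#' printed as 0.480 while 177/370 = 0.478); `printed = TRUE` therefore
#' returns a series carrying the published columns verbatim, which is the
#' pathway used when reproducing published fit parameters, while
#' `printed = FALSE` recomputes F and the logs from the group counts at
#' full precision.
#'
#' @param printed Logical; return published column values (default) or
#'   recompute from counts.
#' @return An `fn_series` object.
#' @export
hta_fn_table <- function(printed = TRUE) {
  path <- system.file("extdata", "china_hta_fn_table.csv", package = "hazfn")
  df <- utils::read.csv(path)
  if (!printed) return(fn_series_from_table(df))
  out <- data.frame(n_deaths = as.integer(df$n_deaths),
                    n_accidents = as.integer(df$n_accidents),
                    F = df$F, lgN = df$lgN, lgF = df$lgF, slope = df$slope)
  structure(out, class = c("fn_series", "data.frame"),
            total_accidents = sum(df$n_accidents))
}
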