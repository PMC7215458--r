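#' @title ALARP criterion lines and risk-zone classification
#' @description
#' The ALARP ("as low as reasonably practicable") framework divides the
#' F-N plane into three zones using two power-law limit lines
#' F = C N^(-a): above the tolerable line the risk is unacceptable, below
#' the acceptable line it is broadly acceptable, and between the two it is
#' tolerable only if reduced as low as reasonably practicable. Points
#' exactly on a line belong to the less severe zone.
#' @name alarp
NULL

#' Risk zones, ordered from least to most severe
#' @export
risk_zones <- c("broadly_acceptable", "tolerable_if_alarp", "unacceptable")

#' Construct a criterion limit line
#'
#' @param a Slope magnitude of the limit line (a = 1 is risk-neutral,
#'   a = 2 risk-averse).
#' @param C Frequency intercept at N = 1.
#' @param label Line label.
#' @return A `criterion_line` object.
#' @export
criterion_line <- function(a, C, label = "custom") {
  stopifnot(a > 0, C > 0)
  structure(list(a = a, C = C, label = label), class = "criterion_line")
}

#' @export
print.criterion_line <- function(x, ...) {
  cat(sprintf("<criterion_line '%s'> F = %g * N^(-%g)\n", x$label, x$C, x$a))
  invisible(x)
}

#' Default ALARP limit lines
#'
#' Risk-neutral lines (a = 1) with a tolerable-line intercept of 0.1 and
#' an acceptable-line intercept 1% of it (0.001).
#'
#' @return A list with `tolerable` and `acceptable` [criterion_line]s.
#' @export
default_lines <- function() {
  list(tolerable = criterion_line(1, 0.1, "tolerable"),
       acceptable = criterion_line(1, 0.001, "acceptable"))
}

line_F <- function(line, N) line$C * N^(-line$a)

#' Classify F-N points into ALARP risk zones
#'
#' @param F Cumulative frequencies (> 0, vectorized).
#' @param N Fatality counts (>= 1).
#' @param lines A list with `tolerable` and `acceptable` [criterion_line]s
#'   (default [default_lines()]).
#' @return A factor over [risk_zones] (ordered, least severe first).
#' @export
classify_zone <- function(F, N, lines = default_lines()) {
  stopifnot(all(F > 0), all(N >= 1))
  tol <- line_F(lines$tolerable, N)
  acc <- line_F(lines$acceptable, N)
  zone <- ifelse(F > tol, "unacceptable",
                 ifelse(F > acc, "tolerable_if_alarp", "broadly_acceptable"))
  factor(zone, levels = risk_zones, ordered = TRUE)
}

#' Fatality count at which a curve crosses a limit line
#'
#' For a curve F = C_c N^(-a_c) and a line F = C_l N^(-a_l) with different
#' slopes, the unique crossing is at
#' `N* = (C_c / C_l)^(1 / (a_c - a_l))`.
#'
#' @param curve A list (or [criterion_line]) with elements `a` and `C`.
#' @param line A [criterion_line].
#' @return The crossing `N*` (possibly < 1, meaning the curve is on one
#'   side of the line over the whole physical range), or `NA` with a
#'   `"degenerate"` attribute message for parallel or identical lines.
#' @export
crossing_fatalities <- function(curve, line) {
  if (curve$a == line$a) {
    msg <- if (curve$C == line$C) "identical line: crossing everywhere"
           else "parallel lines: no finite crossing"
    return(structure(NA_real_, degenerate = msg))
  }
  (curve$C / line$C)^(1 / (curve$a - line$a))
}

#' Assess an F-N band against ALARP limit lines
#'
#' Classifies the central, lower (optimistic) and upper (pessimistic)
#' edges of a band at each supported N, and summarises the central curve
#' by the worst zone it attains. By default the assessment is restricted
#' to the observed N support of the series behind the band; verdicts at
#' extrapolated N require `extrapolate = TRUE`.
#'
#' @param band An `fn_band`.
#' @param lines ALARP lines, as from [default_lines()].
#' @param N Evaluation points; defaults to the N values of the band's
#'   series.
#' @param extrapolate Allow N beyond the observed support.
#' @return A `risk_assessment`: list with `zones` (data frame of per-N
#'   zones per edge), `verdict` (worst central zone), per-edge verdicts,
#'   and `crossings` (N* of each edge against each line).
#' @export
assess_curve <- function(band, lines = default_lines(), N = NULL,
                         extrapolate = FALSE) {
  stopifnot(inherits(band, "fn_band"))
  support <- range(band$series$n_deaths)
  if (is.null(N)) N <- band$series$n_deaths
  if (!extrapolate && any(N < support[1] | N > support[2]))
    stop("N outside observed support [", support[1], ", ", support[2],
         "]; set extrapolate = TRUE to allow")
  ev <- fn_band_eval(band, N)
  zones <- data.frame(
    N = N,
    lower = classify_zone(ev$lower, N, lines),
    central = classify_zone(ev$central, N, lines),
    upper = classify_zone(ev$upper, N, lines)
  )
  worst <- function(z) factor(risk_zones[max(as.integer(z))],
                              levels = risk_zones, ordered = TRUE)
  crossings <- do.call(rbind, lapply(c("lower", "central", "upper"), function(e) {
    data.frame(edge = e,
               line = c("tolerable", "acceptable"),
               N_star = c(crossing_fatalities(band[[e]], lines$tolerable),
                          crossing_fatalities(band[[e]], lines$acceptable)))
  }))
  structure(list(zones = zones,
                 verdict = worst(zones$central),
                 verdict_optimistic = worst(zones$lower),
                 verdict_pessimistic = worst(zones$upper),
                 crossings = crossings,
                 lines = lines),
            class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat("<risk_assessment>\n")
  cat(sprintf("  central verdict (worst zone over support): %s\n", x$verdict))
  cat(sprintf("  optimistic (lower edge): %s; pessimistic (upper edge): %s\n",
              x$verdict_optimistic, x$verdict_pessimistic))
  cat("  crossings (N* where the edge meets each line):\n")
  print.data.frame(x$crossings, row.names = FALSE)
  invisible(x)
}
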