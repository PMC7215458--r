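#' Severity levels of accident consequences
#'
#' China grades production-safety accidents into five levels by death toll,
#' number of serious injuries, and direct economic loss. Level I is an
#' accident without casualties; Level V is the most severe.
#'
#' @format An ordered factor level set, `"I" < "II" < ... < "V"`.
#' @export
severity_levels <- c("I", "II", "III", "IV", "V")

#' Classify an accident's severity level
#'
#' Applies the five-level grading used for production-safety accidents in
#' China. Each of the three consequence dimensions triggers a level on its
#' own and the accident is graded at the most severe level triggered:
#'
#' * deaths: 1-2 -> II, 3-9 -> III, 10-29 -> IV, 30+ -> V
#' * serious injuries: 1-9 -> II, 10-49 -> III, 50-99 -> IV, 100+ -> V
#' * direct economic loss (10^4 yuan): 1000-4999 -> III, 5000-9999 -> IV,
#'   10000+ -> V
#'
#' Boundary values are graded on the more severe side (e.g. exactly 3 deaths
#' is Level III, exactly 30 is Level V). An accident with no deaths, no
#' serious injuries and loss below 10 million yuan is Level I. Loss below
#' 10 million yuan on its own never raises the level above I: the official
#' wording would otherwise make every accident at least Level II.
#'
#' @param deaths Number of deaths (non-negative integer, vectorized).
#' @param serious_injuries Number of serious injuries (non-negative integer).
#' @param economic_loss Direct economic loss in units of 10^4 yuan
#'   (non-negative).
#' @return An ordered factor over [severity_levels].
#' @examples
#' classify_severity(2, 0, 0)    # II
#' classify_severity(35, 0, 0)   # V
#' classify_severity(0, 120, 0)  # V
#' @export
classify_severity <- function(deaths, serious_injuries = 0, economic_loss = 0) {
  n <- max(length(deaths), length(serious_injuries), length(economic_loss))
  deaths <- rep_len(deaths, n)
  serious_injuries <- rep_len(serious_injuries, n)
  economic_loss <- rep_len(economic_loss, n)
  stopifnot(
    is.numeric(deaths), is.numeric(serious_injuries), is.numeric(economic_loss),
    all(!is.na(deaths)), all(!is.na(serious_injuries)), all(!is.na(economic_loss)),
    all(deaths >= 0), all(serious_injuries >= 0), all(economic_loss >= 0)
  )
  lvl_death <- findInterval(deaths, c(1, 3, 10, 30)) + 1L
  lvl_inj <- findInterval(serious_injuries, c(1, 10, 50, 100)) + 1L
  # loss below 1000 (10 million yuan) does not trigger any level
  lvl_loss <- findInterval(economic_loss, c(1000, 5000, 10000)) + 1L
  lvl_loss[lvl_loss > 1L] <- lvl_loss[lvl_loss > 1L] + 1L
  lvl <- pmax(lvl_death, lvl_inj, lvl_loss)
  factor(severity_levels[lvl], levels = severity_levels, ordered = TRUE)
}
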