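#' @title Accident record sets
#' @description
#' An accident record set (`hta_records`) is a data frame with one row per
#' accident and the columns
#' `date` (ISO-8601), `hour` (0-23), `province`, `hazmat_classes`
#' (semicolon-separated ADR classes 1-9, e.g. `"3;8"`), `species`,
#' `accident_type` (`"collision"` or `"non_collision"`), `specific_type`
#' (1-12; 1-7 are collision types, 8-12 non-collision), `cause_factor`
#' (1 environment, 2 management failure, 3 equipment malfunction,
#' 4 driver error), `road_level` (1 highway/high-level, 2 urban, 3 rural),
#' `deaths`, `serious_injuries`, `economic_loss` (10^4 yuan), and a derived
#' `severity_level`.
#' @name hta_records
NULL

.record_columns <- c(
  "date", "hour", "province", "hazmat_classes", "species", "accident_type",
  "specific_type", "cause_factor", "road_level", "deaths", "serious_injuries",
  "economic_loss"
)

.collision_specific_types <- 1:7

parse_hazmat_classes <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(v) {
    v <- suppressWarnings(as.integer(trimws(v)))
    sort(unique(v))
  })
}

new_hta_records <- function(df, provenance = "unknown") {
  structure(df, class = c("hta_records", "data.frame"), provenance = provenance)
}

#' @export
print.hta_records <- function(x, ...) {
  cat(sprintf("<hta_records> %d accidents (provenance: %s)\n",
              nrow(x), attr(x, "provenance")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

validate_records <- function(df) {
  problems <- character(0)
  note <- function(rows, msg) {
    if (length(rows)) sprintf("row %d: %s", rows, msg) else character(0)
  }
  classes <- parse_hazmat_classes(df$hazmat_classes)
  bad_class <- which(vapply(classes, function(v) {
    length(v) == 0 || anyNA(v) || any(v < 1 | v > 9)
  }, logical(1)))
  counts_ok <- function(x) !is.na(x) & x >= 0 & x == floor(x)
  bad_deaths <- which(!counts_ok(df$deaths))
  bad_inj <- which(!counts_ok(df$serious_injuries))
  bad_loss <- which(is.na(df$economic_loss) | df$economic_loss < 0)
  bad_hour <- which(is.na(df$hour) | df$hour < 0 | df$hour > 23)
  bad_date <- which(is.na(as.Date(as.character(df$date), optional = TRUE)))
  bad_spec <- which(is.na(df$specific_type) | !(df$specific_type %in% 1:12))
  bad_cause <- which(is.na(df$cause_factor) | !(df$cause_factor %in% 1:4))
  bad_road <- which(is.na(df$road_level) | !(df$road_level %in% 1:3))
  expected_type <- ifelse(df$specific_type %in% .collision_specific_types,
                          "collision", "non_collision")
  bad_type <- which(!is.na(df$specific_type) & df$specific_type %in% 1:12 &
                      as.character(df$accident_type) != expected_type)
  problems <- c(
    note(bad_class, "hazmat_classes must be a non-empty set of integers 1-9"),
    note(bad_deaths, "deaths must be a non-negative integer"),
    note(bad_inj, "serious_injuries must be a non-negative integer"),
    note(bad_loss, "economic_loss must be non-negative"),
    note(bad_hour, "hour must be in 0-23"),
    note(bad_date, "date is not parsable as ISO-8601"),
    note(bad_spec, "specific_type must be in 1-12"),
    note(bad_cause, "cause_factor must be in 1-4"),
    note(bad_road, "road_level must be in 1-3"),
    note(bad_type, "accident_type inconsistent with specific_type (1-7 collision, 8-12 non-collision)")
  )
  bad_rows <- sort(unique(c(bad_class, bad_deaths, bad_inj, bad_loss, bad_hour,
                            bad_date, bad_spec, bad_cause, bad_road, bad_type)))
  list(bad_rows = bad_rows, problems = problems)
}

#' Read accident records from a delimited text file
#'
#' Reads a comma-separated, UTF-8 file with a header row into a validated
#' [hta_records] set. Rows violating the record invariants are dropped with
#' row-indexed diagnostics (a warning, and the messages in the
#' `"diagnostics"` attribute of the result).
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping the standard column
#'   names (names of the vector) to the column names used in the file.
#' @return An [hta_records] data frame; attribute `"diagnostics"` holds the
#'   per-row rejection messages (empty when all rows are valid).
#' @seealso [write_records()], [expand_multiclass()]
#' @export
read_records <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    missing_map <- setdiff(schema, names(df))
    if (length(missing_map))
      stop("schema refers to absent columns: ", paste(missing_map, collapse = ", "))
    names(df)[match(schema, names(df))] <- names(schema)
  }
  missing_cols <- setdiff(.record_columns, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  df <- df[.record_columns]
  for (col in c("hour", "specific_type", "cause_factor", "road_level",
                "deaths", "serious_injuries"))
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  df$economic_loss <- suppressWarnings(as.numeric(df$economic_loss))
  as_records(df, provenance = path)
}

#' Build a record set from a data frame
#'
#' Validates a data frame against the [hta_records] schema, derives
#' `severity_level`, and drops invalid rows with diagnostics.
#'
#' @param df A data frame with the [hta_records] columns.
#' @param provenance Source label stored with the record set.
#' @return An [hta_records] object.
#' @export
as_records <- function(df, provenance = "data.frame") {
  missing_cols <- setdiff(.record_columns, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  v <- validate_records(df)
  if (length(v$bad_rows)) {
    warning(sprintf("dropped %d invalid row(s); see attr(x, 'diagnostics')",
                    length(v$bad_rows)))
    df <- df[-v$bad_rows, , drop = FALSE]
    rownames(df) <- NULL
  }
  if (nrow(df) == 0) stop("no valid records")
  df$severity_level <- classify_severity(df$deaths, df$serious_injuries,
                                         df$economic_loss)
  out <- new_hta_records(df, provenance = provenance)
  attr(out, "diagnostics") <- v$problems
  out
}

#' Write accident records to a delimited text file
#'
#' @param rs An [hta_records] object.
#' @param path Output CSV path.
#' @export
write_records <- function(rs, path) {
  df <- as.data.frame(rs)
  df$severity_level <- as.character(df$severity_level)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Expand multi-class accidents into single-class cases
#'
#' An accident carrying k hazmat classes becomes k identical cases, each
#' with a single class. This is the preprocessing used before
#' cause-consequence tree modelling, where the class of hazmat is a
#' predictor: the case count at the tree root therefore exceeds the number
#' of accidents when multi-class accidents are present.
#'
#' @param rs An [hta_records] object.
#' @return An [hta_records] object with one row per (accident, class) pair
#'   and singleton `hazmat_classes`; column `accident_id` indexes the source
#'   accident.
#' @export
expand_multiclass <- function(rs) {
  stopifnot(inherits(rs, "hta_records"))
  classes <- parse_hazmat_classes(rs$hazmat_classes)
  k <- lengths(classes)
  idx <- rep(seq_len(nrow(rs)), k)
  out <- as.data.frame(rs)[idx, , drop = FALSE]
  out$hazmat_classes <- as.character(unlist(classes))
  out$accident_id <- idx
  rownames(out) <- NULL
  new_hta_records(out, provenance = paste0(attr(rs, "provenance"), " (expanded)"))
}

#' Frequency table of a categorical record attribute
#'
#' @param rs An [hta_records] object.
#' @param field Name of a categorical column (e.g. `"severity_level"`,
#'   `"cause_factor"`, `"accident_type"`, `"hazmat_classes"`, `"province"`).
#'   For `"hazmat_classes"`, records are expanded to single classes first.
#' @return A data frame with `category`, `count` and `proportion`
#'   (proportions sum to 1).
#' @export
frequency_summary <- function(rs, field) {
  stopifnot(inherits(rs, "hta_records"))
  if (!field %in% names(rs)) stop("unknown field: ", field)
  x <- if (field == "hazmat_classes") expand_multiclass(rs)[[field]] else rs[[field]]
  tab <- table(x)
  data.frame(
    category = names(tab),
    count = as.integer(tab),
    proportion = as.numeric(tab) / sum(tab),
    stringsAsFactors = FALSE
  )
}

#' Day-period labels and hour boundaries
#'
#' Periods partition the day as early morning (12am-6am, hours 0-5),
#' forenoon (6am-12pm, hours 6-11), afternoon (12pm-7pm, hours 12-18) and
#' evening (7pm-12am, hours 19-23).
#' @param hour Integer hour of day (0-23).
#' @return A factor over the four period labels.
#' @export
day_period <- function(hour) {
  labels <- c("early_morning", "forenoon", "afternoon", "evening")
  cut(hour, breaks = c(-1, 5, 11, 18, 23), labels = labels)
}

#' Temporal frequency profile of accidents
#'
#' Counts accidents per hour of day, calendar month, or day period. Bins
#' are dense: empty bins appear with count 0.
#'
#' @param rs An [hta_records] object.
#' @param granularity `"hour"` (0-23), `"month"` (1-12) or `"period"`.
#' @return A data frame with `bin` and `count`.
#' @export
temporal_profile <- function(rs, granularity = c("hour", "month", "period")) {
  stopifnot(inherits(rs, "hta_records"))
  granularity <- match.arg(granularity)
  missing_ts <- sum(is.na(rs$hour) | is.na(rs$date))
  if (missing_ts > 0)
    warning(sprintf("%d record(s) with missing timestamps skipped", missing_ts))
  keep <- !(is.na(rs$hour) | is.na(rs$date))
  x <- switch(granularity,
    hour = factor(rs$hour[keep], levels = 0:23),
    month = factor(as.integer(format(as.Date(rs$date[keep]), "%m")), levels = 1:12),
    period = day_period(rs$hour[keep])
  )
  tab <- table(x)
  data.frame(bin = names(tab), count = as.integer(tab), stringsAsFactors = FALSE)
}

#' Accident rate per unit freight volume
#'
#' Divides per-month accident counts by per-month freight volumes and flags
#' the peak month. The month with the largest ratio can differ from the
#' month with most accidents (low-traffic months inflate the rate).
#'
#' @param counts Per-month accident counts.
#' @param volumes Per-month freight volumes (same length, strictly positive).
#' @return A data frame with `count`, `volume`, `rate` and logical `peak`
#'   (TRUE for the maximal rate).
#' @export
rate_per_volume <- function(counts, volumes) {
  if (length(counts) != length(volumes)) stop("counts and volumes differ in length")
  if (any(is.na(volumes)) || any(volumes <= 0)) stop("volumes must be positive")
  rate <- counts / volumes
  data.frame(count = counts, volume = volumes, rate = rate,
             peak = seq_along(rate) == which.max(rate))
}
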