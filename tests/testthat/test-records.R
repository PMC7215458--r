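test_that("a well-formed file round-trips through read_records", {
  df <- record_df(3, deaths = c(1L, 2L, 3L))
  rs <- read_records(write_record_csv(df))
  expect_s3_class(rs, "hta_records")
  expect_equal(nrow(rs), 3)
  expect_equal(rs$deaths, c(1L, 2L, 3L))
  expect_equal(as.character(rs$severity_level), c("II", "II", "III"))
  expect_length(attr(rs, "diagnostics"), 0)

  tmp <- tempfile(fileext = ".csv")
  write_records(rs, tmp)
  rs2 <- read_records(tmp)
  expect_equal(as.data.frame(rs2)[names(df)], as.data.frame(rs)[names(df)])
})

test_that("semicolon-separated hazmat classes parse into sets", {
  df <- record_df(1, hazmat_classes = "3;8")
  rs <- read_records(write_record_csv(df))
  ex <- expand_multiclass(rs)
  expect_equal(nrow(ex), 2)
  expect_equal(ex$hazmat_classes, c("3", "8"))
})

test_that("invalid rows are rejected with row-indexed diagnostics", {
  df <- record_df(3, deaths = c(1L, -1L, 2L))
  expect_warning(rs <- read_records(write_record_csv(df)), "1 invalid row")
  expect_equal(nrow(rs), 2)
  expect_match(attr(rs, "diagnostics"), "row 2", all = FALSE)

  # inconsistent taxonomy: specific type 8 (rollover) marked collision
  df2 <- record_df(2, specific_type = c(6L, 8L))
  expect_warning(rs2 <- read_records(write_record_csv(df2)), "invalid row")
  expect_equal(nrow(rs2), 1)
})

test_that("missing required columns are a schema error", {
  df <- record_df(2)
  df$deaths <- NULL
  expect_error(read_records(write_record_csv(df)), "deaths")
  # a schema mapping can rename columns
  df <- record_df(2)
  names(df)[names(df) == "deaths"] <- "fatalities"
  rs <- read_records(write_record_csv(df), schema = c(deaths = "fatalities"))
  expect_equal(nrow(rs), 2)
})

test_that("expand_multiclass conserves severity within each case", {
  df <- record_df(1, hazmat_classes = "2;3", deaths = 1L)
  rs <- as_records(df)
  ex <- expand_multiclass(rs)
  expect_equal(nrow(ex), 2)
  expect_equal(as.character(ex$severity_level), c("II", "II"))

  # all-singleton input is unchanged apart from the case index
  rs1 <- as_records(record_df(4))
  ex1 <- expand_multiclass(rs1)
  expect_equal(nrow(ex1), 4)
  expect_equal(ex1$hazmat_classes, rs1$hazmat_classes)
})

test_that("expansion conserves per-level totals over class multiplicity", {
  rs <- generate_records(generator_config(n_accidents = 120, seed = 11))
  ex <- expand_multiclass(rs)
  k <- lengths(strsplit(rs$hazmat_classes, ";"))
  expect_equal(nrow(ex), sum(k))
  for (lvl in unique(as.character(rs$severity_level))) {
    expect_equal(sum(as.character(ex$severity_level) == lvl),
                 sum(k[as.character(rs$severity_level) == lvl]))
  }
})

test_that("frequency summaries report counts and unit-sum proportions", {
  lv <- c(rep("II", 280), rep("III", 91))
  df <- record_df(371, deaths = ifelse(lv == "II", 1L, 5L))
  rs <- as_records(df)
  fs <- frequency_summary(rs, "severity_level")
  expect_equal(fs$count[fs$category == "II"], 280)
  expect_equal(round(100 * fs$proportion[fs$category == "II"], 2), 75.47)
  expect_equal(sum(fs$proportion), 1, tolerance = 1e-9)

  one <- frequency_summary(as_records(record_df(5)), "province")
  expect_equal(one$proportion, 1)
  expect_error(frequency_summary(rs, "no_such_field"), "unknown field")
})

test_that("temporal profiles use dense bins and the four day periods", {
  rs <- as_records(record_df(4, hour = 3L))
  prof <- temporal_profile(rs, "period")
  expect_equal(prof$count[prof$bin == "early_morning"], 4)
  expect_equal(sum(prof$count), 4)

  hourly <- temporal_profile(rs, "hour")
  expect_equal(nrow(hourly), 24)
  expect_equal(hourly$count[hourly$bin == "7"], 0)

  # planted period counts are recovered exactly
  counts <- c(226, 128, 145, 70)
  hours <- rep(c(2L, 9L, 14L, 21L), counts)
  rs2 <- as_records(record_df(sum(counts), hour = hours))
  prof2 <- temporal_profile(rs2, "period")
  expect_equal(prof2$count, counts)
})

test_that("rate per volume is the elementwise ratio with an argmax peak", {
  r <- rate_per_volume(c(10, 10), c(5, 2))
  expect_equal(r$rate, c(2, 5))
  expect_equal(which(r$peak), 2)
  # equal volumes: rates proportional to counts
  r2 <- rate_per_volume(c(3, 9, 6), c(4, 4, 4))
  expect_equal(r2$rate / r2$rate[1], c(1, 3, 2))
  expect_equal(which(r2$peak), which.max(c(3, 9, 6)))
  expect_error(rate_per_volume(c(1, 2), c(1, 0)), "positive")
  expect_error(rate_per_volume(c(1, 2), 1), "length")
})
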