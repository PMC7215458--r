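# Small in-code fixtures shared across tests.

# a well-formed record data frame; override columns via ...
record_df <- function(n = 3, ...) {
  df <- data.frame(
    date = rep("2015-06-01", n),
    hour = rep(3L, n),
    province = rep("Shandong", n),
    hazmat_classes = rep("3", n),
    species = rep("oil", n),
    accident_type = rep("collision", n),
    specific_type = rep(6L, n),
    cause_factor = rep(4L, n),
    road_level = rep(1L, n),
    deaths = rep(1L, n),
    serious_injuries = rep(0L, n),
    economic_loss = rep(10, n),
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

write_record_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# build an fn_series directly from chosen column values (printed-table dialect)
series_from_columns <- function(n_deaths, F, n_accidents = rep(1L, length(n_deaths))) {
  lgN <- log10(n_deaths)
  lgF <- log10(F)
  structure(
    data.frame(n_deaths = n_deaths, n_accidents = n_accidents, F = F,
               lgN = lgN, lgF = lgF,
               slope = ifelse(lgN > 0, lgF / lgN, NA_real_)),
    class = c("fn_series", "data.frame"),
    total_accidents = sum(n_accidents)
  )
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# four well-separated regional cluster profiles
separated_profiles <- function(n = 8, sep = 1) {
  lapply(1:4, function(i) list(
    mean = c(5000, 20000, 100000, 15) * (1 + i * sep),
    sd = c(500, 2000, 10000, 1.5),
    n = n
  ))
}
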