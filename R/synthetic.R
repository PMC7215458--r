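#' @title Synthetic accident-record generation
#' @description
#' Generates accident records with controlled statistical structure:
#' categorical attributes drawn from the observed 2004-2018 China HTA
#' case marginals by default, death tolls from a truncated discrete
#' power law planted on the survival function (so the planted exponent
#' is directly the F-N slope being recovered), and optional planted
#' cause-to-consequence rules for decision-tree recovery experiments.
#' Every generator is deterministic under a fixed seed.
#' @name synthetic_data
NULL

.cn_provinces <- c(
  "Beijing", "Tianjin", "Hebei", "Shanxi", "Inner Mongolia", "Liaoning",
  "Jilin", "Heilongjiang", "Shanghai", "Jiangsu", "Zhejiang", "Anhui",
  "Fujian", "Jiangxi", "Shandong", "Henan", "Hubei", "Hunan", "Guangdong",
  "Guangxi", "Hainan", "Chongqing", "Sichuan", "Guizhou", "Yunnan", "Tibet",
  "Shaanxi", "Gansu", "Qinghai", "Ningxia", "Xinjiang")

.species_by_class <- list(
  `1` = c("fireworks", "detonator"),
  `2` = c("liquefied petroleum gas", "natural gas", "liquid ammonia"),
  `3` = c("oil", "methanol", "benzene", "ethanol"),
  `4` = c("yellow phosphorus", "calcium carbide"),
  `5` = c("ammonium nitrate", "hydrogen peroxide"),
  `6` = c("sodium cyanide", "pesticide"),
  `7` = c("radioactive source"),
  `8` = c("sulfuric acid", "hydrochloric acid", "sodium hydroxide"),
  `9` = c("miscellaneous"))

#' Category marginals of the 2004-2018 China HTA cases
#'
#' Proportions of the 569 single-class accident cases per categorical
#' variable (day period, hazmat class, specific accident type, cause
#' factor, road level, severity level). These are the generator defaults.
#'
#' @return A named list of probability vectors (names are category codes).
#' @export
hta_category_marginals <- function() {
  norm <- function(x) x / sum(x)
  list(
    period = norm(stats::setNames(c(226, 128, 145, 70), 1:4)),
    hazmat_class = norm(stats::setNames(c(12, 108, 317, 11, 3, 34, 0, 84, 0), 1:9)),
    specific_type = norm(stats::setNames(
      c(18, 6, 12, 60, 16, 179, 57, 135, 49, 8, 17, 12), 1:12)),
    cause_factor = norm(stats::setNames(c(50, 42, 44, 433), 1:4)),
    road_level = norm(stats::setNames(c(493, 37, 39), 1:3)),
    severity_level = norm(stats::setNames(c(408, 104, 32, 25),
                                          c("II", "III", "IV", "V")))
  )
}

#' Generator configuration
#'
#' @param n_accidents Number of accidents to generate.
#' @param death_tail_exponent Target power-law slope a* of the F-N
#'   relation of the fatal accidents (default 1.34, the magnitude
#'   observed for the 2004-2018 China series).
#' @param max_deaths Truncation of the death-toll distribution (default
#'   60, mirroring the observed range).
#' @param zero_death_fraction Fraction of non-fatal records (default 0:
#'   the surveyed records are fatal accidents).
#' @param category_marginals Per-variable category probabilities
#'   (default [hta_category_marginals()]).
#' @param class_count_probs Probabilities that an accident carries 1, 2,
#'   3, ... hazmat classes (default `c(0.5, 0.45, 0.05)`, reproducing the
#'   observed expansion of 371 accidents into roughly 569 cases).
#' @param planted_rules Optional named list keyed by cause-factor code;
#'   each element is a probability vector over severity levels that
#'   overrides the consequence distribution of accidents with that cause
#'   (death tolls are then drawn uniformly within the level's death
#'   range).
#' @param region_profiles Optional list of cluster profiles for
#'   [generate_regions()]; each profile is a list with `mean` (length-4:
#'   population, gdp, freight_volume, road_length), `sd` (scalar or
#'   length-4) and `n`.
#' @param count_correlation Target correlation between regional features
#'   and accident counts (default 0.9).
#' @param seed Random seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_accidents = 371, death_tail_exponent = 1.34,
                             max_deaths = 60, zero_death_fraction = 0,
                             category_marginals = hta_category_marginals(),
                             class_count_probs = c(0.5, 0.45, 0.05),
                             planted_rules = NULL, region_profiles = NULL,
                             count_correlation = 0.9, seed = 1) {
  stopifnot(n_accidents >= 1, death_tail_exponent > 0, max_deaths >= 2,
            zero_death_fraction >= 0, zero_death_fraction < 1)
  for (m in category_marginals)
    if (abs(sum(m) - 1) > 1e-8) stop("marginals must sum to 1")
  if (!is.null(planted_rules))
    for (r in planted_rules)
      if (abs(sum(r) - 1) > 1e-8) stop("planted rule probabilities must sum to 1")
  structure(list(n_accidents = n_accidents,
                 death_tail_exponent = death_tail_exponent,
                 max_deaths = max_deaths,
                 zero_death_fraction = zero_death_fraction,
                 category_marginals = category_marginals,
                 class_count_probs = class_count_probs,
                 planted_rules = planted_rules,
                 region_profiles = region_profiles,
                 count_correlation = count_correlation,
                 seed = seed),
            class = "generator_config")
}

#' Death tolls from a truncated discrete power law
#'
#' Draws i.i.d. death counts with survival function
#' `P(deaths >= N) = N^(-a_star)` for N = 1..max_deaths (mass beyond the
#' truncation pooled into the top count). Planting the law on the
#' survival function makes `a_star` directly the log-log slope of the
#' F-N relation of the generated accidents.
#'
#' @param n Number of draws.
#' @param a_star Tail exponent (> 0).
#' @param max_deaths Truncation point.
#' @param seed Optional seed (set only when non-NULL).
#' @return Integer vector of death counts, all >= 1.
#' @export
generate_deaths <- function(n, a_star, max_deaths = 60, seed = NULL) {
  stopifnot(n >= 1, a_star > 0, max_deaths >= 2)
  if (!is.null(seed)) set.seed(seed)
  N <- seq_len(max_deaths)
  surv <- N^(-a_star)
  p <- c(surv[-max_deaths] - surv[-1], surv[max_deaths])
  sample(N, n, replace = TRUE, prob = p)
}

.level_death_range <- list(I = c(0, 0), II = c(1, 2), III = c(3, 9),
                           IV = c(10, 29), V = c(30, Inf))

#' Generate a synthetic accident record set
#'
#' Categorical attributes are independent draws from the configured
#' marginals (accident type is derived from the specific type, so the
#' collision taxonomy invariant always holds); death tolls come from
#' [generate_deaths()]; severity is derived with [classify_severity()].
#' When a planted rule covers a record's cause factor, its severity level
#' is drawn from the rule and the death toll uniformly within that
#' level's death range instead.
#'
#' @param config A [generator_config()].
#' @return An [hta_records] object.
#' @export
generate_records <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_accidents
  m <- config$category_marginals
  draw <- function(marg, k = n) {
    sample(names(marg), k, replace = TRUE, prob = marg)
  }
  period <- as.integer(draw(m$period))
  hour_lo <- c(0, 6, 12, 19)[period]
  hour_hi <- c(5, 11, 18, 23)[period]
  hour <- hour_lo + floor(stats::runif(n) * (hour_hi - hour_lo + 1))
  date <- as.Date("2004-01-01") +
    floor(stats::runif(n) * as.integer(as.Date("2018-12-31") - as.Date("2004-01-01") + 1))
  k_classes <- sample(seq_along(config$class_count_probs), n, replace = TRUE,
                      prob = config$class_count_probs)
  pos_classes <- m$hazmat_class[m$hazmat_class > 0]
  k_classes <- pmin(k_classes, length(pos_classes))
  classes <- vapply(k_classes, function(k) {
    paste(sort(as.integer(sample(names(pos_classes), k, prob = pos_classes))),
          collapse = ";")
  }, "")
  first_class <- vapply(strsplit(classes, ";"), `[`, "", 1)
  species <- vapply(first_class, function(cl) {
    sample(.species_by_class[[cl]], 1)
  }, "", USE.NAMES = FALSE)
  specific_type <- as.integer(draw(m$specific_type))
  accident_type <- ifelse(specific_type %in% .collision_specific_types,
                          "collision", "non_collision")
  cause_factor <- as.integer(draw(m$cause_factor))
  deaths <- generate_deaths(n, config$death_tail_exponent, config$max_deaths)
  if (config$zero_death_fraction > 0) {
    zero <- stats::runif(n) < config$zero_death_fraction
    deaths[zero] <- 0L
  }
  serious_injuries <- stats::rpois(n, 0.3 + 0.2 * deaths)
  economic_loss <- round(stats::rlnorm(n, meanlog = log(50), sdlog = 1), 1)
  if (!is.null(config$planted_rules)) {
    for (cause in names(config$planted_rules)) {
      rule <- config$planted_rules[[cause]]
      idx <- which(cause_factor == as.integer(cause))
      if (!length(idx)) next
      lvl <- sample(names(rule), length(idx), replace = TRUE, prob = rule)
      rng <- .level_death_range[lvl]
      lo <- vapply(rng, `[`, 0, 1)
      hi <- pmin(vapply(rng, `[`, 0, 2), config$max_deaths)
      deaths[idx] <- as.integer(lo + floor(stats::runif(length(idx)) * (hi - lo + 1)))
      serious_injuries[idx] <- 0L
      economic_loss[idx] <- 0
    }
  }
  df <- data.frame(
    date = as.character(date), hour = as.integer(hour),
    province = sample(.cn_provinces, n, replace = TRUE),
    hazmat_classes = classes, species = species,
    accident_type = accident_type, specific_type = specific_type,
    cause_factor = cause_factor,
    road_level = as.integer(draw(m$road_level)),
    deaths = as.integer(deaths),
    serious_injuries = as.integer(serious_injuries),
    economic_loss = economic_loss,
    stringsAsFactors = FALSE)
  as_records(df, provenance = sprintf("synthetic (seed %d)", config$seed))
}

#' Generate synthetic regional feature profiles
#'
#' Draws per-region features from Gaussian cluster profiles and accident
#' counts positively linked to the features through a latent score with
#' configurable correlation.
#'
#' @param config A [generator_config()] with non-NULL `region_profiles`.
#' @return A data frame with `region`, the four feature columns,
#'   `accidents`, and the planted `cluster`.
#' @export
generate_regions <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  profiles <- config$region_profiles
  if (is.null(profiles) || !length(profiles)) stop("no region profiles configured")
  set.seed(config$seed + 1L)
  feat_names <- c("population", "gdp", "freight_volume", "road_length")
  rows <- lapply(seq_along(profiles), function(i) {
    pr <- profiles[[i]]
    sd <- rep_len(pr$sd, 4)
    if (any(sd < 0)) stop("profile sd must be non-negative")
    f <- matrix(stats::rnorm(pr$n * 4, mean = rep(pr$mean, each = pr$n),
                             sd = rep(sd, each = pr$n)), ncol = 4)
    colnames(f) <- feat_names
    cbind(as.data.frame(f), cluster = i)
  })
  df <- do.call(rbind, rows)
  df$region <- sprintf("region_%02d", seq_len(nrow(df)))
  z <- rowMeans(scale(df[feat_names]))
  z <- (z - mean(z)) / max(stats::sd(z), 1e-12)
  rho <- config$count_correlation
  latent <- rho * z + sqrt(max(0, 1 - rho^2)) * stats::rnorm(nrow(df))
  df$accidents <- pmax(0L, as.integer(round(15 + 8 * latent)))
  df[c("region", feat_names, "accidents", "cluster")]
}
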