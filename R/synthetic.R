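#' Configuration for the synthetic burden/economy generator
#'
#' Describes a country of `n_provinces` province-like units laid out on a
#' west-to-east axis, with GDP per capita declining (or rising) along that
#' axis and an age- and sex-structured congenital-heart-anomaly burden whose
#' rate may co-vary with provincial income. The generator exists so that the
#' full valuation pipeline is testable without any external burden export.
#'
#' @param n_provinces Number of province-like units (default 34).
#' @param age_groups Age-stratum labels, ordered young to old.
#' @param base_daly_rate National all-age DALY rate per 100,000 person-years
#'   before provincial modulation (default 96.3).
#' @param male_excess Multiplicative male excess: male rates equal female
#'   rates times `1 + male_excess` before noise (default 0.7, >= 0).
#' @param yld_share Fraction of the DALY burden that is morbidity, in
#'   `[0, 1)`; YLL counts are exactly `(1 - yld_share)` times the DALY
#'   counts (default 0.04).
#' @param gdp_gradient Log-scale spread of GDP per capita across the axis;
#'   0 makes every province equally rich (default 1.5).
#' @param burden_gdp_correlation Sign/strength in `[-1, 1]` of the link
#'   between burden rate and GDP per capita; negative concentrates burden in
#'   poorer (eastern) provinces (default -0.5).
#' @param population_range Length-2 positive vector, min/max provincial
#'   population (default 7e5 to 5e7 persons).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise applied to rates (mean-1 noise; populations are noise-free;
#'   default 0.1).
#' @param seed Integer RNG seed; identical config + seed gives
#'   byte-identical tables.
#' @param age_count_weights Share of burden events per age stratum; defaults
#'   concentrate mass in infancy (`<1`), where congenital heart disease
#'   burden peaks.
#' @param age_pop_shares Population share per age stratum; defaults follow a
#'   broadly Indonesian age pyramid.
#' @param gdp_per_capita_usd Axis-midpoint GDP per capita in USD
#'   (default 4350).
#' @param exchange_rate Local currency units per USD (default 14308).
#' @return A `synthetic_config` object (named list), validated.
#' @export
synthetic_config <- function(n_provinces = 34,
                             age_groups = c("<1", "1-4", "5-14", "15-49", "50+"),
                             base_daly_rate = 96.3,
                             male_excess = 0.7,
                             yld_share = 0.04,
                             gdp_gradient = 1.5,
                             burden_gdp_correlation = -0.5,
                             population_range = c(7e5, 5e7),
                             noise_cv = 0.1,
                             seed = 1L,
                             age_count_weights = NULL,
                             age_pop_shares = NULL,
                             gdp_per_capita_usd = 4350,
                             exchange_rate = 14308) {
  if (!is.numeric(n_provinces) || n_provinces < 1) {
    stop_config("n_provinces", "must be a positive count")
  }
  n_age <- length(age_groups)
  if (n_age < 1) stop_config("age_groups", "must be non-empty")
  if (base_daly_rate < 0) stop_config("base_daly_rate", "must be >= 0")
  if (male_excess < 0) stop_config("male_excess", "must be >= 0")
  if (yld_share < 0 || yld_share >= 1) {
    stop_config("yld_share", "must lie in [0, 1)")
  }
  if (abs(burden_gdp_correlation) > 1) {
    stop_config("burden_gdp_correlation", "must lie in [-1, 1]")
  }
  if (length(population_range) != 2 || any(population_range <= 0) ||
      population_range[1] > population_range[2]) {
    stop_config("population_range", "must be positive with min <= max")
  }
  if (noise_cv < 0) stop_config("noise_cv", "must be >= 0")
  if (gdp_per_capita_usd <= 0) stop_config("gdp_per_capita_usd", "must be > 0")
  if (exchange_rate <= 0) stop_config("exchange_rate", "must be > 0")
  if (is.null(age_count_weights)) {
    age_count_weights <- if (n_age == 5) {
      c(0.55, 0.20, 0.10, 0.10, 0.05)
    } else {
      w <- 0.5^(seq_len(n_age) - 1)
      w / sum(w)
    }
  }
  if (length(age_count_weights) != n_age || any(age_count_weights < 0)) {
    stop_config("age_count_weights", "must be non-negative, one per age group")
  }
  age_count_weights <- age_count_weights / sum(age_count_weights)
  if (is.null(age_pop_shares)) {
    age_pop_shares <- if (n_age == 5) {
      c(0.018, 0.072, 0.17, 0.52, 0.22)
    } else {
      rep(1 / n_age, n_age)
    }
  }
  if (length(age_pop_shares) != n_age || any(age_pop_shares <= 0)) {
    stop_config("age_pop_shares", "must be positive, one per age group")
  }
  age_pop_shares <- age_pop_shares / sum(age_pop_shares)
  structure(
    list(n_provinces = as.integer(n_provinces), age_groups = age_groups,
         base_daly_rate = base_daly_rate, male_excess = male_excess,
         yld_share = yld_share, gdp_gradient = gdp_gradient,
         burden_gdp_correlation = burden_gdp_correlation,
         population_range = population_range, noise_cv = noise_cv,
         seed = as.integer(seed), age_count_weights = age_count_weights,
         age_pop_shares = age_pop_shares,
         gdp_per_capita_usd = gdp_per_capita_usd,
         exchange_rate = exchange_rate),
    class = "synthetic_config"
  )
}

# Deterministic provincial frame shared by the burden and economy generators:
# axis positions, populations (drawn first so both generators see the same
# draws), and GDP per capita along the west-east gradient.
synth_frame <- function(config) {
  n <- config$n_provinces
  set.seed(config$seed)
  pop <- stats::runif(n, config$population_range[1], config$population_range[2])
  u <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0.5
  tibble::tibble(
    province = sprintf("Province %02d", seq_len(n)),
    axis = u,
    population = pop,
    gdp_per_capita_usd = config$gdp_per_capita_usd *
      exp(config$gdp_gradient * (u - 0.5))
  )
}

#' Generate synthetic burden cells
#'
#' Emits one cell per (province, sex, age group, measure) with rate per
#' 100,000, population and absolute count. Female rates follow the
#' provincial modulation `exp(corr * gradient * (axis - 0.5))` so that with
#' `burden_gdp_correlation = -1` the provincial burden ranking exactly
#' reverses the GDP-per-capita ranking; male rates are `1 + male_excess`
#' times the female rates before noise; combined-sex counts are the sum of
#' the sex-specific counts (never drawn independently); YLL counts are
#' exactly `(1 - yld_share)` times DALY counts, sharing the same noise draw.
#'
#' @param config A [synthetic_config()].
#' @return Tibble of burden cells with columns `province`, `sex`,
#'   `age_group`, `measure`, `rate`, `population`, `count`, `cause`, `year`.
#' @export
#' @examples
#' cells <- generate_burden(synthetic_config(n_provinces = 3, seed = 7))
generate_burden <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  frame <- synth_frame(config)
  n <- config$n_provinces
  n_age <- length(config$age_groups)

  # expected female counts per cell; equal sex split keeps the male/female
  # count ratio equal to the rate ratio
  mod <- exp(config$burden_gdp_correlation * config$gdp_gradient *
               (frame$axis - 0.5))
  pop_sex <- frame$population / 2
  base_f <- outer(config$base_daly_rate / 1e5 * mod * pop_sex,
                  config$age_count_weights)

  noise <- function() {
    if (config$noise_cv == 0) return(matrix(1, n, n_age))
    s <- sqrt(log(1 + config$noise_cv^2))
    matrix(stats::rlnorm(n * n_age, meanlog = -s^2 / 2, sdlog = s), n, n_age)
  }
  cnt_f <- base_f * noise()
  cnt_m <- base_f * (1 + config$male_excess) * noise()

  cell_grid <- function(counts, sex, pop_sex_total) {
    pop_cell <- outer(pop_sex_total, config$age_pop_shares)
    tibble::tibble(
      province = rep(frame$province, times = n_age),
      sex = sex,
      age_group = rep(config$age_groups, each = n),
      population = as.vector(pop_cell),
      count = as.vector(counts)
    )
  }
  daly <- dplyr::bind_rows(
    cell_grid(cnt_f, "female", pop_sex),
    cell_grid(cnt_m, "male", pop_sex),
    cell_grid(cnt_f + cnt_m, "both", frame$population)
  )
  daly$measure <- "DALY"
  yll <- daly
  yll$measure <- "YLL"
  yll$count <- yll$count * (1 - config$yld_share)

  dplyr::bind_rows(daly, yll) |>
    dplyr::mutate(
      rate = .data$count / .data$population * 1e5,
      cause = "Congenital heart anomalies",
      year = 2021L
    ) |>
    dplyr::select("province", "sex", "age_group", "measure", "rate",
                  "population", "count", "cause", "year") |>
    dplyr::arrange(.data$measure, .data$province, .data$sex, .data$age_group)
}

#' Generate the matching synthetic economy table
#'
#' One record per province with GDP exactly equal to GDP per capita times
#' population, in USD and in local currency at the configured exchange rate.
#' Populations are identical to those underlying [generate_burden()] for the
#' same config.
#'
#' @param config A [synthetic_config()].
#' @return Tibble with `province`, `gdp_local`, `gdp_usd`,
#'   `gdp_per_capita_usd`, `population`.
#' @export
generate_economy <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  frame <- synth_frame(config)
  frame |>
    dplyr::mutate(
      gdp_usd = .data$gdp_per_capita_usd * .data$population,
      gdp_local = .data$gdp_usd * config$exchange_rate
    ) |>
    dplyr::select("province", "gdp_local", "gdp_usd", "gdp_per_capita_usd",
                  "population")
}
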