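#' Sex-specific life-expectancy table
#'
#' Flat life expectancies (years) used as the divisor when converting a value
#' of a statistical life (VSL) into a value per statistical life year (VSLY).
#' Defaults are the 2021 Indonesian values: 60.67 years for males, 73.55 for
#' females and 73.5 for the total population. An age-specific divisor table
#' can be emulated by monetizing age strata separately with different tables.
#'
#' @param male,female,both Life expectancy in years; all must be positive.
#' @return An object of class `life_expectancy_table`: a named numeric vector
#'   with entries `male`, `female`, `both`.
#' @export
#' @examples
#' le <- life_expectancy_table()
#' le[["male"]]
life_expectancy_table <- function(male = 60.67, female = 73.55, both = 73.5) {
  out <- c(male = male, female = female, both = both)
  if (any(!is.finite(out)) || any(out <= 0)) {
    stop_config("life_expectancy", "all entries must be positive and finite")
  }
  structure(out, class = c("life_expectancy_table", "numeric"))
}

le_years <- function(le, sex) {
  bad <- setdiff(unique(sex), names(le))
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("No life expectancy for sex label(s): %s",
              paste(sQuote(bad), collapse = ", ")),
      class = "vlw_vocabulary_error"
    )
  }
  unname(unclass(le)[sex])
}

#' Benefit transfer of a value of a statistical life
#'
#' Rescales a reference country's VSL to a target setting through the ratio
#' of GDP per capita raised to an income elasticity:
#' \deqn{VSL_{target} = VSL_{ref} \times
#'   (GDP^{pc}_{target} / GDP^{pc}_{ref})^{\varepsilon}}
#' An elasticity of 1.0 (unit income elasticity) is the conventional choice
#' when transferring to lower- and middle-income settings.
#'
#' @param vsl_reference Reference VSL in USD (> 0).
#' @param gdp_target_pc,gdp_reference_pc GDP per capita (USD/person, > 0) for
#'   the target and reference economies.
#' @param elasticity Income elasticity of VSL (>= 0); default 1.
#' @return Transferred VSL in USD.
#' @export
#' @examples
#' transfer_vsl(10e6, 1200, 10000, elasticity = 1)  # 1.2e6
transfer_vsl <- function(vsl_reference, gdp_target_pc, gdp_reference_pc,
                         elasticity = 1) {
  if (any(vsl_reference <= 0)) stop_config("vsl_reference", "must be > 0")
  if (any(gdp_target_pc <= 0)) stop_config("gdp_target_pc", "must be > 0")
  if (any(gdp_reference_pc <= 0)) stop_config("gdp_reference_pc", "must be > 0")
  if (any(elasticity < 0)) stop_config("elasticity", "must be >= 0")
  vsl_reference * (gdp_target_pc / gdp_reference_pc)^elasticity
}

#' Define a VSL valuation benchmark
#'
#' A benchmark is either `native` (estimated directly for the target economy,
#' e.g. from a hedonic wage model) or `transferred` (a reference VSL rescaled
#' by [transfer_vsl()]). When the transfer parameters are supplied, `vsl_usd`
#' may be omitted (it is computed) or, if given, must agree with the transfer
#' to within 0.5% — otherwise the benchmark is internally inconsistent.
#'
#' @param name Benchmark label (e.g. `"wage"`, `"oecd"`, `"usdot"`).
#' @param vsl_usd VSL in USD (> 0). Optional when the transfer parameters are
#'   supplied.
#' @param provenance `"native"` or `"transferred"`.
#' @param vsl_reference_usd,gdp_target_pc,gdp_reference_pc,elasticity
#'   Benefit-transfer parameters (transferred benchmarks only).
#' @return A `vsl_benchmark` object (a named list).
#' @seealso [default_benchmarks()], [transfer_vsl()]
#' @export
vsl_benchmark <- function(name, vsl_usd = NULL,
                          provenance = c("native", "transferred"),
                          vsl_reference_usd = NULL,
                          gdp_target_pc = NULL, gdp_reference_pc = NULL,
                          elasticity = 1) {
  provenance <- match.arg(provenance)
  has_transfer <- !is.null(vsl_reference_usd) && !is.null(gdp_target_pc) &&
    !is.null(gdp_reference_pc)
  if (provenance == "transferred" && has_transfer) {
    implied <- transfer_vsl(vsl_reference_usd, gdp_target_pc,
                            gdp_reference_pc, elasticity)
    if (is.null(vsl_usd)) {
      vsl_usd <- implied
    } else if (abs(vsl_usd - implied) > 0.005 * implied) {
      stop_config("vsl_usd", sprintf(
        "inconsistent with benefit transfer of the stored parameters (%.0f vs %.0f)",
        vsl_usd, implied))
    }
  }
  if (is.null(vsl_usd)) {
    stop_config("vsl_usd", "must be supplied (or derivable from transfer parameters)")
  }
  if (!is.numeric(vsl_usd) || vsl_usd <= 0) stop_config("vsl_usd", "must be > 0")
  structure(
    list(name = name, vsl_usd = vsl_usd, provenance = provenance,
         vsl_reference_usd = vsl_reference_usd,
         gdp_target_pc = gdp_target_pc, gdp_reference_pc = gdp_reference_pc,
         elasticity = elasticity),
    class = "vsl_benchmark"
  )
}

#' Default VSL benchmarks
#'
#' Three benchmarks for Indonesia: a national hedonic-wage estimate
#' (US\$950,000) and two income-transferred references, one OECD-based
#' (US\$1.2 million) and one based on the US Department of Transportation
#' guidance (US\$1.77 million), both transferred at unit income elasticity.
#' The transferred values are stored as given; reference-side parameters of
#' the transfer are not part of the defaults.
#'
#' @return Named list of [vsl_benchmark()] objects: `wage`, `oecd`, `usdot`.
#' @export
#' @examples
#' vapply(default_benchmarks(), function(b) b$vsl_usd, numeric(1))
default_benchmarks <- function() {
  list(
    wage  = vsl_benchmark("wage", 950000, "native"),
    oecd  = vsl_benchmark("oecd", 1200000, "transferred"),
    usdot = vsl_benchmark("usdot", 1770000, "transferred")
  )
}

#' Value per statistical life year
#'
#' Divides a benchmark's VSL by the sex-specific life expectancy, giving the
#' per-life-year price used to monetize DALYs and YLLs. Sex-specific
#' divisors mean a male life year is priced higher than a female life year
#' under the same VSL (shorter male life expectancy).
#'
#' @param benchmark A [vsl_benchmark()].
#' @param sex Character vector of sex labels (`"male"`, `"female"`, `"both"`).
#' @param le A [life_expectancy_table()].
#' @return A tibble with columns `benchmark`, `sex`, `vsly_usd`.
#' @export
#' @examples
#' vsly(vsl_benchmark("wage", 950000), "both")  # 950000 / 73.5
vsly <- function(benchmark, sex, le = life_expectancy_table()) {
  stopifnot(inherits(benchmark, "vsl_benchmark"))
  per_year <- benchmark$vsl_usd / le_years(le, sex)
  tibble::tibble(
    benchmark = benchmark$name,
    sex = sex,
    vsly_usd = per_year
  )
}

#' Monetize burden cells into value of lost welfare
#'
#' For each (province, sex, measure) the welfare loss is the sum over age
#' strata of the absolute burden count times the sex-specific VSLY:
#' \deqn{VLW_{i,s,m} = \sum_\alpha B_{i,s,\alpha} \times VSLY_{m,s}}
#' Combined-sex rows are monetized with the combined-sex VSLY applied to the
#' combined counts — not as the sum of the male and female losses, which
#' would double-price male life years.
#'
#' @param cells Burden cells: a data frame with columns `province`, `sex`,
#'   `measure`, and `count` (absolute events); if `count` is absent it is
#'   derived as `rate / 1e5 * population`.
#' @param benchmark A [vsl_benchmark()].
#' @param le A [life_expectancy_table()].
#' @return Tibble with `province`, `sex`, `measure`, `benchmark`,
#'   `vlw_billion_usd` (billion USD, full precision).
#' @export
monetize <- function(cells, benchmark, le = life_expectancy_table()) {
  stopifnot(inherits(benchmark, "vsl_benchmark"))
  cells <- tibble::as_tibble(cells)
  if (!"count" %in% names(cells) || anyNA(cells$count)) {
    if (!all(c("rate", "population") %in% names(cells))) {
      rlang::abort(
        "Burden cells carry no `count` and no `rate` + `population` to derive it.",
        class = "vlw_data_error"
      )
    }
    cells$count <- cells$rate / 1e5 * cells$population
  }
  cells |>
    dplyr::mutate(
      sex = normalize_sex(.data$sex),
      measure = normalize_measure(.data$measure),
      vsly_usd = benchmark$vsl_usd / le_years(le, .data$sex)
    ) |>
    dplyr::summarise(
      vlw_billion_usd = sum(.data$count * .data$vsly_usd) / 1e9,
      .by = c("province", "sex", "measure")
    ) |>
    dplyr::mutate(benchmark = benchmark$name, .before = "vlw_billion_usd") |>
    dplyr::arrange(.data$measure, .data$province, .data$sex)
}

#' Combined-sex welfare loss from sex-specific losses
#'
#' Because each sex is monetized with its own life-expectancy divisor while
#' the combined row uses the combined divisor over the summed counts, the
#' combined-sex VLW satisfies
#' \deqn{VLW_{both} = (VLW_{male} LE_{male} + VLW_{female} LE_{female}) / LE_{both}}
#' and is therefore smaller than the male + female sum. This identity lets
#' the combined figure be recovered from published sex-specific figures.
#'
#' @param vlw_male,vlw_female Sex-specific VLW (same unit, e.g. billion USD).
#' @param le A [life_expectancy_table()].
#' @return Combined-sex VLW in the input unit.
#' @export
#' @examples
#' combine_sex_vlw(6.931, 3.309)  # ~9.03 billion
combine_sex_vlw <- function(vlw_male, vlw_female, le = life_expectancy_table()) {
  (vlw_male * le[["male"]] + vlw_female * le[["female"]]) / le[["both"]]
}

#' Rescale welfare losses to a different VSL benchmark
#'
#' VLW is linear in the VSL, so losses under one benchmark map to another by
#' the ratio of the two VSLs; no re-monetization is needed.
#'
#' @param vlw Numeric VLW values computed under benchmark `from`.
#' @param from,to [vsl_benchmark()] objects.
#' @return `vlw * to$vsl_usd / from$vsl_usd`.
#' @export
rescale_benchmark <- function(vlw, from, to) {
  stopifnot(inherits(from, "vsl_benchmark"), inherits(to, "vsl_benchmark"))
  vlw * to$vsl_usd / from$vsl_usd
}

#' Welfare loss as a share of GDP
#'
#' Joins provincial welfare losses to provincial GDP and expresses the loss
#' as a percentage of GDP.
#'
#' @param loss Tibble with `province` and `vlw_billion_usd` (and any keys).
#' @param econ Tibble with `province` and `gdp_usd` (USD).
#' @return `loss` with an added `ratio_percent` column (100 x VLW / GDP).
#' @export
vlw_to_gdp <- function(loss, econ) {
  unmatched <- setdiff(unique(loss$province), econ$province)
  if (length(unmatched) > 0) {
    rlang::abort(
      sprintf("No economic record for province(s): %s",
              paste(sQuote(unmatched), collapse = ", ")),
      class = "vlw_join_error"
    )
  }
  if (any(econ$gdp_usd <= 0)) {
    rlang::abort("GDP must be positive for every province.",
                 class = "vlw_data_error")
  }
  loss |>
    dplyr::left_join(dplyr::select(econ, "province", "gdp_usd"),
                     by = "province") |>
    dplyr::mutate(ratio_percent = 100 * .data$vlw_billion_usd * 1e9 / .data$gdp_usd) |>
    dplyr::select(-"gdp_usd")
}

#' Relative gap between DALY- and YLL-based welfare losses
#'
#' The gap is the share of the DALY-based loss not explained by premature
#' mortality: \eqn{100 (VLW_{DALY} - VLW_{YLL}) / VLW_{DALY}}. With
#' YLL <= DALY cell-wise the gap lies in [0, 100) and equals the morbidity
#' (YLD) share of the monetized burden.
#'
#' @param vlw_daly,vlw_yll Either numeric vectors of matching length, or two
#'   data frames keyed by `province`, `sex`, `benchmark` with a
#'   `vlw_billion_usd` column.
#' @return Numeric gap in percent, or (for data-frame input) the joined
#'   tibble with a `gap_percent` column.
#' @export
#' @examples
#' daly_yll_gap(0.042, 0.037)  # ~11.9, the largest provincial gap
daly_yll_gap <- function(vlw_daly, vlw_yll) {
  if (is.numeric(vlw_daly) && is.numeric(vlw_yll)) {
    if (any(vlw_daly == 0)) {
      rlang::abort("Gap undefined where the DALY-based VLW is zero.",
                   class = "vlw_data_error")
    }
    return(100 * (vlw_daly - vlw_yll) / vlw_daly)
  }
  keys <- intersect(c("province", "sex", "benchmark"),
                    intersect(names(vlw_daly), names(vlw_yll)))
  joined <- dplyr::inner_join(
    dplyr::select(vlw_daly, dplyr::all_of(keys), vlw_daly = "vlw_billion_usd"),
    dplyr::select(vlw_yll, dplyr::all_of(keys), vlw_yll = "vlw_billion_usd"),
    by = keys
  )
  if (any(joined$vlw_daly == 0)) {
    rlang::abort("Gap undefined where the DALY-based VLW is zero.",
                 class = "vlw_data_error")
  }
  dplyr::mutate(joined,
                gap_percent = 100 * (.data$vlw_daly - .data$vlw_yll) / .data$vlw_daly)
}
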