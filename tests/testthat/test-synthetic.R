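test_that("generator is deterministic in the seed and sensitive to it", {
  cfg <- synthetic_config(n_provinces = 6, seed = 1L)
  expect_identical(generate_burden(cfg), generate_burden(cfg))
  expect_identical(generate_economy(cfg), generate_economy(cfg))
  cfg2 <- synthetic_config(n_provinces = 6, seed = 2L)
  expect_false(identical(generate_burden(cfg), generate_burden(cfg2)))
})

test_that("male excess and morbidity share are forced by construction", {
  cfg <- quiet_config(male_excess = 1.0)
  cells <- generate_burden(cfg)
  wide <- tidyr::pivot_wider(
    cells[cells$sex != "both", c("province", "sex", "age_group", "measure", "rate")],
    names_from = "sex", values_from = "rate")
  expect_equal(wide$male, 2 * wide$female)

  cfg0 <- quiet_config(yld_share = 0)
  cells0 <- generate_burden(cfg0)
  daly <- cells0[cells0$measure == "DALY", ]
  yll <- cells0[cells0$measure == "YLL", ]
  expect_equal(daly$count, yll$count)
  expect_equal(daly$rate, yll$rate)

  # YLL never exceeds DALY cell-wise under a positive morbidity share
  cells <- generate_burden(quiet_config(yld_share = 0.3, noise_cv = 0.2))
  d <- cells[cells$measure == "DALY", ]
  y <- cells[cells$measure == "YLL", ]
  expect_true(all(y$count <= d$count))
})

test_that("combined-sex counts equal male plus female in every cell", {
  cells <- generate_burden(synthetic_config(n_provinces = 8, seed = 3L))
  wide <- tidyr::pivot_wider(
    cells[, c("province", "sex", "age_group", "measure", "count")],
    names_from = "sex", values_from = "count")
  expect_equal(wide$both, wide$male + wide$female)
})

test_that("economy table obeys the GDP identity and gradient settings", {
  cfg <- synthetic_config(n_provinces = 7, seed = 5L)
  econ <- generate_economy(cfg)
  expect_equal(econ$gdp_usd, econ$gdp_per_capita_usd * econ$population)
  expect_equal(econ$gdp_usd / econ$population, econ$gdp_per_capita_usd)
  expect_equal(econ$gdp_local, econ$gdp_usd * cfg$exchange_rate)
  expect_true(all(econ$gdp_usd > 0))

  flat <- generate_economy(synthetic_config(n_provinces = 7, gdp_gradient = 0,
                                            seed = 5L))
  expect_equal(length(unique(flat$gdp_per_capita_usd)), 1L)
})

test_that("perfect negative burden-GDP link reverses the provincial ranking", {
  cfg <- quiet_config(burden_gdp_correlation = -1, n_provinces = 10, seed = 9L)
  cells <- generate_burden(cfg)
  econ <- generate_economy(cfg)
  both <- cells[cells$sex == "both" & cells$measure == "DALY", ]
  all_age_rate <- vapply(
    split(both, both$province),
    function(d) sum(d$count) / sum(d$population) * 1e5, numeric(1))
  expect_identical(order(all_age_rate[econ$province]),
                   rev(order(econ$gdp_per_capita_usd)))
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(synthetic_config(yld_share = 1), "yld_share",
               class = "vlw_config_error")
  expect_error(synthetic_config(yld_share = -0.1), "yld_share")
  expect_error(synthetic_config(male_excess = -1), "male_excess")
  expect_error(synthetic_config(population_range = c(-1, 10)),
               "population_range")
  expect_error(synthetic_config(burden_gdp_correlation = 2),
               "burden_gdp_correlation")
  expect_error(synthetic_config(noise_cv = -0.2), "noise_cv")
})

test_that("generated tables round-trip through the burden reader", {
  cfg <- synthetic_config(n_provinces = 4, seed = 13L)
  cells <- generate_burden(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_burden_table(cells, path)
  back <- read_burden_table(path, metric = "Rate")
  key <- c("province", "sex", "age_group", "measure")
  cells_o <- dplyr::arrange(cells, dplyr::across(dplyr::all_of(key)))
  back_o <- dplyr::arrange(back, dplyr::across(dplyr::all_of(key)))
  expect_equal(back_o[names(cells_o)], cells_o)

  # population derivable from the Rate/Number twin rows when not written
  write_burden_table(cells, path, include_population = FALSE)
  back2 <- read_burden_table(path, metric = "Number")
  back2_o <- dplyr::arrange(back2, dplyr::across(dplyr::all_of(key)))
  expect_equal(back2_o$population, cells_o$population, tolerance = 1e-12)
  expect_equal(back2_o$count, cells_o$count, tolerance = 1e-12)
})
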