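test_that("benefit transfer follows the income-elasticity formula", {
  expect_equal(transfer_vsl(5e6, 1200, 60000, elasticity = 0), 5e6)
  expect_equal(transfer_vsl(5e6, 4300, 4300, elasticity = 1), 5e6)
  expect_equal(transfer_vsl(1e7, 1200, 10000, elasticity = 1), 1.2e6)
  # degree-1 homogeneity in the GDP ratio at unit elasticity
  expect_equal(transfer_vsl(1e7, 2 * 1200, 10000, 1),
               2 * transfer_vsl(1e7, 1200, 10000, 1))
  expect_error(transfer_vsl(1e7, -1, 10000), class = "vlw_config_error")
  expect_error(transfer_vsl(1e7, 1200, 10000, elasticity = -1),
               class = "vlw_config_error")
})

test_that("transferred benchmarks enforce internal consistency", {
  b <- vsl_benchmark("oecd", provenance = "transferred",
                     vsl_reference_usd = 1e7, gdp_target_pc = 1200,
                     gdp_reference_pc = 10000, elasticity = 1)
  expect_equal(b$vsl_usd, 1.2e6)
  expect_error(
    vsl_benchmark("oecd", vsl_usd = 9e6, provenance = "transferred",
                  vsl_reference_usd = 1e7, gdp_target_pc = 1200,
                  gdp_reference_pc = 10000),
    "inconsistent", class = "vlw_config_error")
  expect_error(vsl_benchmark("x", vsl_usd = -1), class = "vlw_config_error")
})

test_that("VSLY divides the VSL by the sex-specific life expectancy", {
  wage <- vsl_benchmark("wage", 950000)
  expect_equal(vsly(wage, "both")$vsly_usd, 12925.17, tolerance = 1e-6)
  expect_equal(vsly(wage, "male")$vsly_usd, 15658.48, tolerance = 1e-6)
  unit <- life_expectancy_table(male = 1, female = 1, both = 1)
  expect_equal(vsly(wage, "female", unit)$vsly_usd, 950000)
  expect_error(vsly(wage, "unknown"), class = "vlw_vocabulary_error")
})

test_that("monetization prices counts at the sex-specific VSLY", {
  wage <- vsl_benchmark("wage", 950000)
  cells <- tibble::tibble(province = "A", sex = "male", age_group = "<1",
                          measure = "DALY", count = 100000)
  out <- monetize(cells, wage)
  expect_equal(out$vlw_billion_usd, 1.5658, tolerance = 1e-4)

  zero <- dplyr::mutate(cells, count = 0)
  expect_equal(monetize(zero, wage)$vlw_billion_usd, 0)

  # counts derived from rate and population when absent
  rated <- tibble::tibble(province = "A", sex = "male", age_group = "<1",
                          measure = "DALY", rate = 96.3, population = 1e6)
  expect_equal(monetize(rated, wage)$vlw_billion_usd,
               963 * 950000 / 60.67 / 1e9)
  expect_error(monetize(dplyr::select(rated, -"rate"), wage),
               class = "vlw_data_error")
})

test_that("monetization is additive over age strata and provinces", {
  wage <- vsl_benchmark("wage", 950000)
  cells <- generate_burden(synthetic_config(n_provinces = 4, seed = 21L))
  out <- monetize(cells, wage)
  split_ages <- monetize(cells[cells$age_group == "<1", ], wage)
  rest <- monetize(cells[cells$age_group != "<1", ], wage)
  joined <- dplyr::inner_join(split_ages, rest,
                              by = c("province", "sex", "measure", "benchmark"))
  total <- dplyr::inner_join(joined, out,
                             by = c("province", "sex", "measure", "benchmark"))
  expect_equal(total$vlw_billion_usd.x + total$vlw_billion_usd.y,
               total$vlw_billion_usd)
})

test_that("welfare losses scale linearly in the VSL across benchmarks", {
  cells <- generate_burden(synthetic_config(n_provinces = 5, seed = 8L))
  bm <- default_benchmarks()
  vlw_wage <- monetize(cells, bm$wage)
  vlw_usdot <- monetize(cells, bm$usdot)
  expect_equal(vlw_usdot$vlw_billion_usd,
               vlw_wage$vlw_billion_usd * 1.77 / 0.95)
  expect_equal(rescale_benchmark(vlw_wage$vlw_billion_usd, bm$wage, bm$usdot),
               vlw_usdot$vlw_billion_usd)
})

test_that("combined-sex VLW obeys the life-expectancy weighted identity", {
  le <- life_expectancy_table()
  cells <- generate_burden(synthetic_config(n_provinces = 5, seed = 31L))
  out <- monetize(cells, default_benchmarks()$oecd, le)
  wide <- tidyr::pivot_wider(out, names_from = "sex",
                             values_from = "vlw_billion_usd")
  expect_equal(wide$both * le[["both"]],
               wide$male * le[["male"]] + wide$female * le[["female"]])
  # hence both < male + female
  expect_true(all(wide$both < wide$male + wide$female))
  expect_equal(combine_sex_vlw(wide$male, wide$female, le), wide$both)
})

test_that("VLW-to-GDP ratios divide losses by provincial GDP", {
  loss <- tibble::tibble(province = c("A", "B"), sex = "both",
                         measure = "DALY", benchmark = "wage",
                         vlw_billion_usd = c(1, 0))
  econ <- tibble::tibble(province = c("A", "B"), gdp_usd = c(100e9, 50e9))
  out <- vlw_to_gdp(loss, econ)
  expect_equal(out$ratio_percent, c(1, 0))
  expect_error(vlw_to_gdp(dplyr::mutate(loss, province = c("A", "Z")), econ),
               "Z", class = "vlw_join_error")
})

test_that("the DALY-YLL gap is the morbidity share of the DALY-based loss", {
  expect_equal(daly_yll_gap(1, 1), 0)
  expect_equal(round_half_up(daly_yll_gap(0.042, 0.037)), 12)
  expect_equal(daly_yll_gap(0.096, 0.090), 6.25)
  expect_error(daly_yll_gap(0, 1), class = "vlw_data_error")

  d <- tibble::tibble(province = "A", sex = "both", benchmark = "wage",
                      vlw_billion_usd = 2)
  y <- dplyr::mutate(d, vlw_billion_usd = 1.9)
  expect_equal(daly_yll_gap(d, y)$gap_percent, 5)
})
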