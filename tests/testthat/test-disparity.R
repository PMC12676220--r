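test_that("gender disparity is the male excess relative to females", {
  expect_equal(gender_disparity(0.061, 0.016), 281.25)
  expect_equal(gender_disparity(0.157, 0.059), 166.10, tolerance = 1e-4)
  expect_equal(gender_disparity(5, 5), 0)
  expect_error(gender_disparity(1, 0), class = "vlw_data_error")
})

test_that("location quotient compares burden share to population share", {
  expect_equal(location_quotient(0.2, 1, 0.2, 1), 1)
  expect_equal(location_quotient(0.10, 1, 0.05, 1), 2)
  # a single-province nation always has LQ 1
  expect_equal(location_quotient(7.3, 7.3, 4e6, 4e6), 1)
  expect_error(location_quotient(1, 1, 2, 1), class = "vlw_data_error")
  expect_error(location_quotient(1, 0, 1, 2), class = "vlw_data_error")
})

test_that("population-weighted mean LQ is 1 on any full partition", {
  for (seed in 1:10) {
    cfg <- synthetic_config(n_provinces = 34, seed = seed)
    cells <- generate_burden(cfg)
    econ <- generate_economy(cfg)
    vlw <- monetize(cells[cells$sex == "both" & cells$measure == "DALY", ],
                    default_benchmarks()$wage)
    vlw <- vlw[match(econ$province, vlw$province), ]
    lq <- location_quotient(vlw$vlw_billion_usd, sum(vlw$vlw_billion_usd),
                            econ$population, sum(econ$population))
    expect_equal(sum(econ$population / sum(econ$population) * lq), 1)
  }
})

test_that("disparity index rescales ratios by the national reference", {
  expect_equal(disparity_index(1.2, 1.2), 1)
  expect_equal(disparity_index(3.6, 1.2), 3)
  expect_equal(disparity_index(0, 1.2), 0)
  expect_error(disparity_index(1, 0), class = "vlw_data_error")
})

test_that("well-separated values cluster into ordered groups", {
  vals <- tibble::tibble(
    province = letters[1:8],
    value = c(1, 2, 101, 102, 201, 202, 301, 302))
  cl <- classify_clusters(vals, k = 4)
  expect_equal(cl$cluster, rep(1:4, each = 2))
  expect_equal(as.character(cl$cluster_label[1:2]), rep("very low", 2))
  expect_equal(as.character(cl$cluster_label[7:8]), rep("very high", 2))
  expect_true(is.ordered(cl$cluster_label))
  # identical input -> identical labels
  expect_identical(classify_clusters(vals, k = 4), cl)
})

test_that("degenerate inputs with too few distinct values are rejected", {
  expect_error(classify_clusters(stats::setNames(rep(1, 6), letters[1:6]), k = 4),
               class = "vlw_cluster_error")
  expect_error(classify_clusters(c(a = 1, b = 1, c = 2), k = 3),
               class = "vlw_cluster_error")
})

test_that("clustering attains the brute-force optimum on small inputs", {
  set.seed(42)
  for (n in c(4, 7, 10, 12)) {
    for (k in 1:4) {
      for (rep in 1:3) {
        x <- round(stats::runif(n, 0, 100), 1)
        if (length(unique(x)) < k) next
        cl <- classify_clusters(stats::setNames(x, paste0("p", seq_len(n))), k,
                                labels = paste0("c", seq_len(k)))
        ours <- clustering_summary(cl)
        oracle <- oracle_kmeans_1d(x, k)
        expect_equal(ours$wcss, oracle$wcss, tolerance = 1e-9)
        expect_true(any(vapply(oracle$bounds, identical, logical(1),
                               as.numeric(ours$bounds))))
      }
    }
  }
})

test_that("noiseless synthetic data recovers the closed-form gender disparity", {
  mu <- 0.8
  cfg <- quiet_config(male_excess = mu, n_provinces = 6)
  cells <- generate_burden(cfg)
  vlw <- monetize(cells, default_benchmarks()$wage)
  wide <- tidyr::pivot_wider(vlw, names_from = "sex",
                             values_from = "vlw_billion_usd")
  gd <- gender_disparity(wide$male, wide$female)
  expect_equal(gd, rep(100 * ((1 + mu) * 73.55 / 60.67 - 1), nrow(wide)))
})
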