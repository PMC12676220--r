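#' Gender disparity in welfare loss
#'
#' Male-female relative difference, expressed as the proportional excess
#' burden among males: \eqn{100 (VLW_m - VLW_f) / VLW_f}. At full precision
#' the statistic is invariant to the VSL benchmark, since both arguments
#' scale by the same constant.
#'
#' @param vlw_male,vlw_female Sex-specific VLW values (same unit).
#' @return Percent excess of the male over the female loss.
#' @export
#' @examples
#' gender_disparity(0.061, 0.016)  # 281.25
gender_disparity <- function(vlw_male, vlw_female) {
  if (any(vlw_female <= 0)) {
    rlang::abort("Gender disparity undefined where the female VLW is zero or negative.",
                 class = "vlw_data_error")
  }
  100 * (vlw_male - vlw_female) / vlw_female
}

#' Location quotient of welfare loss
#'
#' A province's share of the national welfare loss divided by its share of
#' the national population. Values above 1 flag a disproportionate burden
#' relative to population size.
#'
#' @param vlw_province,vlw_national Provincial and national VLW (same unit).
#' @param pop_province,pop_national Provincial and national population.
#' @return Dimensionless location quotient.
#' @export
#' @examples
#' location_quotient(0.10, 1, 0.05, 1)  # 2
location_quotient <- function(vlw_province, vlw_national,
                              pop_province, pop_national) {
  if (any(vlw_national <= 0) || any(pop_national <= 0)) {
    rlang::abort("National VLW and population must be positive.",
                 class = "vlw_data_error")
  }
  pop_share <- pop_province / pop_national
  if (any(pop_share > 1 + 1e-12)) {
    rlang::abort("Provincial population exceeds the national population.",
                 class = "vlw_data_error")
  }
  (vlw_province / vlw_national) / pop_share
}

#' Disparity index of VLW-to-GDP ratios
#'
#' Provincial VLW-to-GDP ratio divided by a national reference ratio; 1
#' means the province's relative burden matches the national benchmark.
#'
#' @param ratio_province,ratio_national VLW-to-GDP ratios in percent.
#' @return Dimensionless index.
#' @export
disparity_index <- function(ratio_province, ratio_national) {
  if (any(ratio_national <= 0)) {
    rlang::abort("Disparity index undefined for a non-positive national ratio.",
                 class = "vlw_data_error")
  }
  ratio_province / ratio_national
}

# Exact 1-D k-means by dynamic programming over the sorted values.
# Optimal 1-D partitions are contiguous in sorted order, so minimizing the
# within-cluster sum of squares reduces to an O(k n^2) DP with prefix sums.
# Ties between split points resolve to the smallest left boundary.
# Returns cluster indices 1..k already ordered by ascending centroid.
kmeans_1d_exact <- function(x, k) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs)
  css <- cumsum(xs^2)
  ssq <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- css[j] - if (i > 1) css[i - 1] else 0
    max(s2 - s^2 / (j - i + 1), 0)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)
  for (j in seq_len(n)) D[1, j] <- ssq(1, j)
  if (k > 1) {
    for (q in 2:k) {
      for (j in q:n) {
        for (m in q:j) {
          cand <- D[q - 1, m - 1] + ssq(m, j)
          if (cand < D[q, j] - 1e-12) {
            D[q, j] <- cand
            B[q, j] <- m
          }
        }
      }
    }
  }
  assign_sorted <- integer(n)
  j <- n
  for (q in k:1) {
    m <- if (q > 1) B[q, j] else 1L
    assign_sorted[m:j] <- q
    j <- m - 1L
  }
  out <- integer(n)
  out[ord] <- assign_sorted
  out
}

#' Cluster disparity values into ordered severity groups
#'
#' One-dimensional k-means computed exactly (dynamic programming over the
#' sorted values, which contains the optimum because optimal 1-D clusters
#' are contiguous in sorted order), then relabeled by ascending centroid
#' onto an ordered label set. The solver is deterministic and globally
#' optimal, so no random initialization or restarts are involved; `seed` is
#' accepted for interface stability but unused.
#'
#' @param values A data frame whose first two columns are (unit, value), or
#'   a named numeric vector.
#' @param k Number of clusters (default 4).
#' @param labels Ordered labels, lowest cluster first; default for `k = 4`
#'   is `c("very low", "low", "high", "very high")`.
#' @param seed Ignored (the solver is deterministic); present so configs
#'   that request random restarts keep a stable signature.
#' @return Tibble with `province`, `value`, `cluster` (integer, ascending
#'   centroid) and `cluster_label` (ordered factor).
#' @export
#' @examples
#' classify_clusters(c(a = 1, b = 2, c = 101, d = 102), k = 2,
#'                   labels = c("low", "high"))
classify_clusters <- function(values, k = 4, labels = NULL, seed = NULL) {
  if (is.data.frame(values)) {
    province <- as.character(values[[1]])
    x <- as.numeric(values[[2]])
  } else {
    x <- as.numeric(values)
    province <- names(values) %||% as.character(seq_along(x))
  }
  if (any(!is.finite(x))) {
    rlang::abort("Disparity values must be finite.", class = "vlw_data_error")
  }
  k <- as.integer(k)
  if (k < 1) stop_config("k", "must be a positive count")
  if (length(unique(x)) < k) {
    rlang::abort(
      sprintf("Need at least k = %d distinct values to form %d clusters (got %d).",
              k, k, length(unique(x))),
      class = "vlw_cluster_error"
    )
  }
  if (is.null(labels)) {
    labels <- if (k == 4) c("very low", "low", "high", "very high")
              else paste("cluster", seq_len(k))
  }
  if (length(labels) != k) stop_config("labels", "must supply one label per cluster")
  cl <- kmeans_1d_exact(x, k)
  tibble::tibble(
    province = province,
    value = x,
    cluster = cl,
    cluster_label = factor(labels[cl], levels = labels, ordered = TRUE)
  )
}
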