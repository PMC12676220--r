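# Brute-force oracle for 1-D k-means: enumerate every partition of the
# sorted values into k contiguous non-empty blocks and minimize the total
# within-cluster sum of squares. Returns the minimal WCSS and all optimal
# block-boundary vectors (boundaries are cumulative block ends).
oracle_kmeans_1d <- function(x, k) {
  n <- length(x)
  xs <- sort(x)
  block_wcss <- function(v) sum((v - mean(v))^2)
  best <- Inf
  best_bounds <- list()
  combs <- if (k == 1) matrix(numeric(0), nrow = 0, ncol = 1)
           else utils::combn(n - 1, k - 1)
  for (ci in seq_len(ncol(combs))) {
    bounds <- c(0, combs[, ci], n)
    w <- 0
    for (b in seq_len(k)) {
      w <- w + block_wcss(xs[(bounds[b] + 1):bounds[b + 1]])
    }
    if (w < best - 1e-9) {
      best <- w
      best_bounds <- list(bounds)
    } else if (abs(w - best) <= 1e-9) {
      best_bounds <- c(best_bounds, list(bounds))
    }
  }
  list(wcss = best, bounds = best_bounds)
}

# Block boundaries and WCSS implied by a classify_clusters() result.
clustering_summary <- function(cl) {
  sizes <- table(cl$cluster[order(cl$value)])
  bounds <- c(0, cumsum(as.integer(sizes)))
  wcss <- sum(vapply(split(cl$value, cl$cluster),
                     function(v) sum((v - mean(v))^2), numeric(1)))
  list(bounds = bounds, wcss = wcss)
}

# Small noiseless config used across tests.
quiet_config <- function(..., noise_cv = 0, n_provinces = 5, seed = 11L) {
  synthetic_config(n_provinces = n_provinces, noise_cv = noise_cv,
                   seed = seed, ...)
}
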