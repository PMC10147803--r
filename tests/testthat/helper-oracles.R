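# Independent oracles and fixture builders, deliberately naive.

# Triple-loop FCM objective, independent of the vectorized implementation.
naive_objective <- function(x, v, u, m) {
  total <- 0
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(nrow(v))) {
      total <- total + u[i, j]^m * sum((x[i, ] - v[j, ])^2)
    }
  }
  total
}

# Brute-force Lloyd k-means from given initial centroids.
lloyd_kmeans <- function(x, centers, max_iter = 100) {
  for (it in seq_len(max_iter)) {
    d2 <- sapply(seq_len(nrow(centers)), function(j) {
      rowSums(sweep(x, 2L, centers[j, ], "-")^2)
    })
    assign <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(nrow(centers))) {
      if (any(assign == j)) {
        new_centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
      }
    }
    if (max(abs(new_centers - centers)) < 1e-12) break
    centers <- new_centers
  }
  list(assign = assign, centers = centers)
}

# Textbook between/within sum-of-squares decomposition.
brute_anova <- function(groups) {
  y <- unlist(groups)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  k <- length(groups)
  n <- length(y)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE),
       ssb = ssb, ssw = ssw)
}

# Two well-separated isotropic clouds in d dimensions.
make_clouds <- function(n_per = 50, d = 6, sep = 5, sd = 0.3, seed = 1) {
  set.seed(seed)
  rbind(matrix(stats::rnorm(n_per * d, -sep, sd), n_per, d),
        matrix(stats::rnorm(n_per * d, sep, sd), n_per, d))
}

# Minimal patient records in the canonical schema.
make_records <- function(n = 3, etiology = "congenital",
                         age = seq(2, 8, length.out = n),
                         cobb = seq(40, 90, length.out = n),
                         kyph = seq(20, 60, length.out = n),
                         lc = rep(5L, n), lk = rep(6L, n)) {
  data.frame(subject_id = sprintf("s%02d", seq_len(n)),
             etiology = etiology, age_years = age, cobb_major_deg = cobb,
             kyphosis_deg = kyph, levels_cobb = lc, levels_kyphosis = lk,
             stringsAsFactors = FALSE)
}

# Small three-component cohort spec (same shape as the shipped defaults but
# lighter, for fast pipeline tests).
small_spec <- function(etiology = "congenital", n = 120,
                       outlier_fraction = 0, seed = 1) {
  means <- list(c(1.5, 35, 27, 4, 5), c(5, 65, 38, 8, 9),
                c(8.5, 95, 45, 12, 13))
  comps <- lapply(seq_along(means), function(j) {
    cluster_spec(weight = c(0.34, 0.33, 0.33)[j], mean = means[[j]],
                 sd = c(0.5, 5, 5, 0.8, 0.8))
  })
  cohort_spec(etiology, n, comps, outlier_fraction = outlier_fraction,
              seed = seed)
}
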