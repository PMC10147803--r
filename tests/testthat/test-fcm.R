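test_that("membership updates follow the inverse-distance-ratio rule", {
  v <- rbind(c(0, 0), c(4, 0), c(0, 4))
  # point exactly on centroid 1 -> crisp singleton
  expect_equal(as.numeric(update_memberships(rbind(c(0, 0)), v, m = 2)),
               c(1, 0, 0))
  # equidistant point between 2 centroids, m = 2 -> symmetric split
  v2 <- rbind(c(-1, 0), c(1, 0))
  expect_equal(as.numeric(update_memberships(rbind(c(0, 0)), v2, m = 2)),
               c(0.5, 0.5))
  # distances (1, 3), m = 2: u1 = 1/(1 + (1/3)^2) = 9/10
  v3 <- rbind(c(1, 0), c(3, 0))
  u <- update_memberships(rbind(c(0, 0)), v3, m = 2)
  expect_equal(as.numeric(u), c(0.9, 0.1), tolerance = 1e-12)
})

test_that("a point coincident with several centroids splits membership equally", {
  v <- rbind(c(0, 0), c(0, 0), c(5, 5))
  u <- update_memberships(rbind(c(0, 0)), v, m = 2)
  expect_equal(as.numeric(u), c(0.5, 0.5, 0))
})

test_that("membership rows are stochastic for random inputs", {
  set.seed(7)
  for (i in 1:10) {
    x <- matrix(rnorm(40 * 6), 40, 6)
    v <- matrix(rnorm(4 * 6), 4, 6)
    m <- runif(1, 1.2, 3)
    u <- update_memberships(x, v, m)
    expect_true(all(u >= 0 & u <= 1))
    expect_equal(rowSums(u), rep(1, 40), tolerance = 1e-9)
  }
})

test_that("centroid updates are weighted means inside the convex hull", {
  # crisp memberships reduce to per-cluster arithmetic means for any m
  x <- rbind(c(0, 0), c(2, 0), c(10, 10), c(12, 10))
  u <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  for (m in c(1.5, 2, 3)) {
    v <- update_centroids(x, u, m)
    expect_equal(v, rbind(c(1, 0), c(11, 10)), ignore_attr = TRUE)
  }
  # uniform memberships over two 1-d points 0 and 4 -> both centroids at 2
  x1 <- matrix(c(0, 4), 2, 1)
  u1 <- matrix(0.5, 2, 2)
  expect_equal(as.numeric(update_centroids(x1, u1, m = 2)), c(2, 2))
  # single point, single cluster: centroid equals the point
  expect_equal(as.numeric(update_centroids(matrix(3, 1, 1),
                                           matrix(1, 1, 1), m = 2)), 3)
  # convex hull containment on random input
  set.seed(3)
  x2 <- matrix(runif(60), 20, 3)
  u2 <- matrix(rexp(20 * 3), 20, 3)
  u2 <- u2 / rowSums(u2)
  v2 <- update_centroids(x2, u2, m = 2)
  expect_true(all(v2 >= apply(x2, 2, min) - 1e-12))
  expect_true(all(v2 <= apply(x2, 2, max) + 1e-12))
})

test_that("the objective matches a naive double-sum oracle", {
  # crisp points on their centroids -> 0
  x <- rbind(c(0, 0), c(5, 5))
  u <- diag(2)
  expect_identical(fcm_objective(x, x, u, m = 2), 0)
  # one point at distance 2 with full membership, m = 2 -> 4
  expect_equal(fcm_objective(rbind(c(2, 0)), rbind(c(0, 0)),
                             matrix(1, 1, 1), m = 2), 4)
  set.seed(11)
  for (i in 1:5) {
    x <- matrix(rnorm(20 * 6), 20, 6)
    v <- matrix(rnorm(3 * 6), 3, 6)
    u <- matrix(rexp(20 * 3), 20, 3)
    u <- u / rowSums(u)
    m <- runif(1, 1.3, 2.5)
    expect_equal(fcm_objective(x, v, u, m), naive_objective(x, v, u, m),
                 tolerance = 1e-9)
  }
})

test_that("fcm recovers well-separated clouds with confident memberships", {
  x <- make_clouds(n_per = 100, sep = 5, sd = 0.3, seed = 2)
  fit <- fcm(x, k = 2, seed = 9)
  cen <- fit$centroids[order(fit$centroids[, 1]), ]
  expect_true(max(abs(cen[1, ] - (-5))) < 0.2)
  expect_true(max(abs(cen[2, ] - 5)) < 0.2)
  expect_gt(average_membership(fit$memberships), 0.95)
  expect_true(fit$converged)
})

test_that("duplicating every point leaves the centroids unchanged", {
  x <- make_clouds(n_per = 40, seed = 4)
  f1 <- fcm(x, k = 2, seed = 1)
  f2 <- fcm(rbind(x, x), k = 2, seed = 1)
  ord1 <- order(f1$centroids[, 1])
  ord2 <- order(f2$centroids[, 1])
  expect_equal(f1$centroids[ord1, ], f2$centroids[ord2, ],
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("fits are deterministic given a seed", {
  x <- make_clouds(seed = 6)
  f1 <- fcm(x, k = 3, seed = 123)
  f2 <- fcm(x, k = 3, seed = 123)
  expect_identical(f1$objective_trace, f2$objective_trace)
  expect_identical(f1$centroids, f2$centroids)
  expect_identical(f1$memberships, f2$memberships)
})

test_that("the objective trace never increases", {
  set.seed(21)
  for (i in 1:6) {
    x <- matrix(rnorm(60 * 4), 60, 4)
    fit <- fcm(x, k = sample(2:4, 1), m = runif(1, 1.5, 2.5),
               seed = i, n_starts = 3)
    expect_true(all(diff(fit$objective_trace) <= 1e-10))
  }
})

test_that("permuting rows permutes memberships and keeps centroids (fixed start)", {
  x <- make_clouds(n_per = 30, seed = 8)
  init <- rbind(x[1, ], x[31, ])
  fit <- fcm(x, k = 2, init = init)
  perm <- sample(nrow(x))
  fit_p <- fcm(x[perm, ], k = 2, init = init)
  expect_equal(fit_p$memberships, fit$memberships[perm, ], tolerance = 1e-9)
  expect_equal(fit_p$centroids, fit$centroids, tolerance = 1e-9)
})

test_that("near-crisp fcm (m = 1.05) agrees with a Lloyd k-means oracle", {
  x <- make_clouds(n_per = 60, sep = 4, sd = 0.5, seed = 13)
  init <- rbind(x[5, ] + 0.3, x[70, ] - 0.3)
  fit <- fcm(x, k = 2, m = 1.05, init = init)
  km <- lloyd_kmeans(x, init)
  fcm_assign <- max.col(fit$memberships, ties.method = "first")
  expect_identical(fcm_assign, km$assign)
})

test_that("degenerate inputs are rejected", {
  expect_error(fcm(matrix(1:4, 2, 2), k = 3), "at least k")
  x <- matrix(rnorm(20), 10, 2)
  x[3, 1] <- NA
  expect_error(fcm(x, k = 2), "non-finite")
  x[3, 1] <- Inf
  expect_error(fcm(x, k = 2), "non-finite")
})
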