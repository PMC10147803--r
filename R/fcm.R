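# Fuzzy C-means (Bezdek alternating optimization) on a numeric matrix.
# Update rules, objective, and the seeded multi-start fitting loop.

# Squared Euclidean distances between rows of x (n x d) and v (k x d).
squared_distances <- function(x, v) {
  d2 <- matrix(rowSums(x^2), nrow(x), nrow(v)) +
    matrix(rowSums(v^2), nrow(x), nrow(v), byrow = TRUE) -
    2 * tcrossprod(x, v)
  pmax(d2, 0)  # guard tiny negatives from cancellation
}

#' Fuzzy membership update
#'
#' Given centroids `v`, assigns each row of `x` graded memberships across the
#' k clusters by the standard fuzzy C-means rule with Euclidean distance:
#' `u_ij = 1 / sum_l (d_ij / d_il)^(2/(m-1))`. A point at (numerically) zero
#' distance from one or more centroids receives membership split equally
#' among the coincident centroids and zero elsewhere.
#'
#' @param x Numeric matrix, n x d (typically standardized features).
#' @param v Centroid matrix, k x d, k >= 2.
#' @param m Fuzzifier, > 1. With `m = 2` memberships are inverse-square
#'   distance ratios.
#' @return An n x k row-stochastic matrix with entries in \[0, 1\].
#' @export
update_memberships <- function(x, v, m = 2) {
  stopifnot(is.matrix(x), is.matrix(v), ncol(x) == ncol(v),
            nrow(v) >= 2L, m > 1)
  d2 <- squared_distances(x, v)
  zero <- d2 < .Machine$double.eps
  u <- d2^(-1 / (m - 1))
  u <- u / rowSums(u)
  hit <- rowSums(zero) > 0L
  if (any(hit)) {
    u[hit, ] <- zero[hit, , drop = FALSE] /
      rowSums(zero[hit, , drop = FALSE])
  }
  u
}

#' Fuzzy centroid update
#'
#' Each centroid is the membership-weighted mean of the data,
#' `v_j = sum_i u_ij^m x_i / sum_i u_ij^m`, so it always lies in the convex
#' hull of `x`. A cluster whose total weight collapses to zero is rescued by
#' re-seating its centroid on the point with the worst current maximum
#' membership (logged via a message).
#'
#' @param x Numeric matrix, n x d.
#' @param u Membership matrix, n x k, rows summing to 1.
#' @param m Fuzzifier, > 1 (crisp 0/1 memberships reduce to per-cluster
#'   arithmetic means for any m).
#' @return A k x d centroid matrix.
#' @export
update_centroids <- function(x, u, m = 2) {
  stopifnot(is.matrix(x), is.matrix(u), nrow(x) == nrow(u), m > 1)
  um <- u^m
  w <- colSums(um)
  empty <- w < .Machine$double.eps
  v <- crossprod(um, x) / w
  if (any(empty)) {
    message(sprintf("empty-cluster rescue triggered for %d cluster(s)",
                    sum(empty)))
    worst <- order(apply(u, 1L, max))[seq_len(sum(empty))]
    v[empty, ] <- x[worst, , drop = FALSE]
  }
  unname(v)
}

#' Fuzzy C-means objective
#'
#' The fuzzified within-cluster scatter `J = sum_i sum_j u_ij^m ||x_i -
#' v_j||^2` that the alternating updates monotonically decrease. Zero exactly
#' when every point sits on a centroid it fully belongs to.
#'
#' @inheritParams update_memberships
#' @param u Membership matrix, n x k.
#' @return A scalar >= 0.
#' @export
fcm_objective <- function(x, v, u, m = 2) {
  stopifnot(nrow(x) == nrow(u), nrow(v) == ncol(u), ncol(x) == ncol(v))
  sum(u^m * squared_distances(x, v))
}

# One FCM run from an initial membership matrix; returns list with the
# fitted pieces plus the per-iteration objective trace.
fcm_single <- function(x, u, m, tol, max_iter) {
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  v <- update_centroids(x, u, m)
  repeat {
    iter <- iter + 1L
    u_new <- update_memberships(x, v, m)
    v <- update_centroids(x, u_new, m)
    trace <- c(trace, fcm_objective(x, v, u_new, m))
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  list(centroids = v, memberships = u, objective = trace[length(trace)],
       objective_trace = trace, converged = converged, n_iter = iter)
}

#' Fit fuzzy C-means
#'
#' Alternates membership and centroid updates from `n_starts` random
#' initializations (row-stochastic memberships drawn from a symmetric
#' Dirichlet(1), seeded) until the largest membership change falls below
#' `tol` or `max_iter` is reached, and keeps the start with the lowest final
#' objective. Runs are deterministic given `seed`. When `x` is a standardized
#' [build_feature_matrix()] result, centroids are also reported in original
#' units via the stored scaling.
#'
#' @param x Numeric matrix (n x d) or standardized `"feature_matrix"`.
#' @param k Number of clusters, `2 <= k <= n`.
#' @param m Fuzzifier, > 1. Default 2.
#' @param tol Convergence tolerance on `max |u - u_prev|`. Default 1e-6.
#' @param max_iter Iteration cap per start. Default 300.
#' @param n_starts Number of random restarts. Default 10.
#' @param seed Integer seed for the initial memberships; `NULL` leaves the
#'   RNG state alone.
#' @param init Optional k x d matrix of initial centroids; when supplied a
#'   single deterministic run starts from it and `n_starts`/`seed` are
#'   ignored.
#' @return An object of class `"fcm"`: list with `k`, `m`, `centroids`
#'   (standardized space when applicable), `centroids_raw` (original units,
#'   when scaling is known), `memberships` (n x k), `objective`,
#'   `objective_trace`, `converged`, `n_iter`, `seed`, `scaling`, plus the
#'   data's `subject_ids`/`etiology` when present.
#' @seealso [predict.fcm()], [select_k()], [flag_outliers()]
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60, -3, 0.4), ncol = 2),
#'            matrix(rnorm(60,  3, 0.4), ncol = 2))
#' fit <- fcm(x, k = 2, seed = 7)
#' fit
#' @export
fcm <- function(x, k, m = 2, tol = 1e-6, max_iter = 300, n_starts = 10,
                seed = NULL, init = NULL) {
  xm <- unclass(x)
  attrs <- attributes(x)
  xm <- matrix(as.numeric(xm), nrow(xm), ncol(xm),
               dimnames = dimnames(xm))
  if (!all(is.finite(xm))) stop("x contains non-finite values")
  n <- nrow(xm)
  stopifnot(k >= 2L, m > 1, tol > 0, max_iter >= 1L, n_starts >= 1L)
  if (n < k) stop(sprintf("need at least k = %d rows, got %d", k, n))

  if (!is.null(init)) {
    stopifnot(is.matrix(init), nrow(init) == k, ncol(init) == ncol(xm))
    u0 <- update_memberships(xm, init, m)
    best <- fcm_single(xm, u0, m, tol, max_iter)
    seed <- NA_integer_
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    best <- NULL
    for (s in seq_len(n_starts)) {
      u0 <- matrix(stats::rexp(n * k), n, k)
      u0 <- u0 / rowSums(u0)
      run <- fcm_single(xm, u0, m, tol, max_iter)
      if (is.null(best) || run$objective < best$objective) best <- run
    }
  }

  scaling <- attrs$scaling
  colnames(best$centroids) <- colnames(xm)
  centroids_raw <- if (!is.null(scaling)) {
    destandardize(best$centroids, scaling)
  } else NULL
  structure(list(
    k = as.integer(k), m = m,
    centroids = best$centroids,
    centroids_raw = centroids_raw,
    memberships = best$memberships,
    objective = best$objective,
    objective_trace = best$objective_trace,
    converged = best$converged,
    n_iter = best$n_iter,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    tol = tol, max_iter = as.integer(max_iter),
    n_starts = as.integer(n_starts),
    scaling = scaling,
    subject_ids = attrs$subject_ids,
    etiology = attrs$etiology,
    n = n
  ), class = "fcm")
}

#' @export
print.fcm <- function(x, ...) {
  cat(sprintf("Fuzzy C-means fit: k = %d, m = %g, n = %d%s\n",
              x$k, x$m, x$n,
              if (!is.null(x$etiology)) paste0(" (", x$etiology, ")") else ""))
  cat(sprintf("  objective %.6g after %d iteration(s)%s\n",
              x$objective, x$n_iter,
              if (x$converged) "" else " [not converged]"))
  cat(sprintf("  average maximum membership: %.3f\n",
              average_membership(x$memberships)))
  invisible(x)
}

#' @export
summary.fcm <- function(object, ...) {
  hard <- hard_assignments(object$memberships)
  out <- list(
    k = object$k, m = object$m, n = object$n,
    etiology = object$etiology,
    objective = object$objective,
    converged = object$converged,
    avg_membership = average_membership(object$memberships),
    cluster_sizes = tabulate(hard, nbins = object$k),
    centroids = if (!is.null(object$centroids_raw)) object$centroids_raw
                else object$centroids)
  class(out) <- "summary.fcm"
  out
}

#' @export
print.summary.fcm <- function(x, ...) {
  cat(sprintf("Fuzzy C-means: k = %d, m = %g, n = %d\n", x$k, x$m, x$n))
  cat(sprintf("  objective %.6g (converged: %s)\n", x$objective, x$converged))
  cat(sprintf("  average maximum membership: %.3f\n", x$avg_membership))
  cat("  cluster sizes (argmax membership):",
      paste(x$cluster_sizes, collapse = ", "), "\n")
  cat("  centroids", if (is.null(x$etiology)) "" else "(original units)", ":\n")
  print(round(x$centroids, 2))
  invisible(x)
}

#' @export
coef.fcm <- function(object, units = c("raw", "standardized"), ...) {
  units <- match.arg(units)
  if (units == "raw" && !is.null(object$centroids_raw)) {
    object$centroids_raw
  } else {
    object$centroids
  }
}

#' @export
fitted.fcm <- function(object, ...) object$memberships

#' Memberships and crisp labels for new data under a frozen model
#'
#' Evaluates the fuzzy membership of new rows against the fitted centroids
#' without refitting. If the model was fitted on standardized features and
#' `newdata` is in original units, the stored scaling is applied first.
#'
#' @param object An `"fcm"` fit.
#' @param newdata Numeric matrix with the same columns the model was fitted
#'   on; omitted to return in-sample values.
#' @param raw Is `newdata` in original (unstandardized) units? Default `TRUE`
#'   when the model stores a scaling.
#' @param ... Unused.
#' @return List with `membership` (n x k), `cluster` (argmax label), and
#'   `max_membership`.
#' @export
predict.fcm <- function(object, newdata = NULL, raw = !is.null(object$scaling),
                        ...) {
  if (is.null(newdata)) {
    u <- object$memberships
  } else {
    z <- as.matrix(newdata)
    if (raw) {
      if (is.null(object$scaling)) stop("model stores no scaling")
      z <- apply_scaling(z, object$scaling)
    }
    u <- update_memberships(z, object$centroids, object$m)
  }
  list(membership = u,
       cluster = hard_assignments(u),
       max_membership = apply(u, 1L, max))
}

# Crisp labels: argmax membership, ties to the lower cluster index.
hard_assignments <- function(u) {
  max.col(u, ties.method = "first")
}
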