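# Cluster-count selection by average membership, membership-floor outlier
# flagging, and canonical ascending-Cobb relabeling.

#' Average membership of a fuzzy partition
#'
#' The per-subject confidence score is the subject's maximum membership; the
#' partition-level score is its mean over subjects. Crisp partitions score 1;
#' a totally uninformative partition over k clusters scores 1/k. This is the
#' quantity maximized when choosing the number of clusters, and the same
#' per-subject score is compared against the outlier floor.
#'
#' @param u Membership matrix (n x k), rows summing to 1.
#' @return A scalar in (0, 1].
#' @export
average_membership <- function(u) {
  stopifnot(is.matrix(u), nrow(u) >= 1L)
  mean(apply(u, 1L, max))
}

#' Flag low-membership subjects as outliers
#'
#' A subject whose maximum membership is strictly below `floor` does not
#' belong convincingly to any cluster and is flagged; flagged subjects are
#' excluded from summary tables and statistics but the model is not refitted
#' by default. The default floor of 0.6 is the conventional lower bound for
#' a confident fuzzy assignment. Raising the floor can only flag more
#' subjects, never fewer.
#'
#' @param u Membership matrix (n x k).
#' @param floor Membership lower bound in (0, 1). Default 0.6. A subject at
#'   exactly `floor` is retained (strict inequality).
#' @return Logical vector, `TRUE` for outliers.
#' @export
flag_outliers <- function(u, floor = 0.6) {
  stopifnot(is.numeric(floor), length(floor) == 1L, floor > 0, floor < 1)
  apply(u, 1L, max) < floor
}

#' Select the number of clusters by maximum average membership
#'
#' Fits fuzzy C-means for each candidate k (identical seed and configuration
#' for every k), scores each fit by [average_membership()], and keeps the k
#' with the highest score; ties break to the smaller k (parsimony). Candidate
#' values of k exceeding n - 1 are skipped with a warning. A best score at or
#' below the uninformative baseline `1/best_k + 0.1` is reported as weak
#' structure via a message.
#'
#' @param x Numeric matrix or standardized `"feature_matrix"`.
#' @param k_range Integer candidates, default `2:6`.
#' @param m,tol,max_iter,n_starts,seed Passed to [fcm()]; the same `seed` is
#'   used for every k.
#' @param floor Membership floor used for the outlier flags of the winning
#'   model. Default 0.6.
#' @return An object of class `"fcm_selection"`: list with `candidate_ks`,
#'   `avg_membership_by_k` (named numeric), `best_k`, `model` (the winning
#'   `"fcm"` fit), `models` (all fits, named by k), `outlier_flags` (from the
#'   winning model at `floor`), and `floor`.
#' @export
select_k <- function(x, k_range = 2:6, m = 2, tol = 1e-6, max_iter = 300,
                     n_starts = 10, seed = NULL, floor = 0.6) {
  n <- nrow(x)
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(all(k_range >= 2L))
  feasible <- k_range <= n - 1L
  if (!all(feasible)) {
    warning(sprintf("skipping k > n - 1 = %d: %s", n - 1L,
                    paste(k_range[!feasible], collapse = ", ")))
    k_range <- k_range[feasible]
  }
  if (length(k_range) == 0L) stop("no feasible k in k_range")

  models <- lapply(k_range, function(k) {
    fcm(x, k = k, m = m, tol = tol, max_iter = max_iter,
        n_starts = n_starts, seed = seed)
  })
  names(models) <- as.character(k_range)
  avg <- vapply(models, function(f) average_membership(f$memberships),
                numeric(1))
  best_idx <- which(avg >= max(avg) - 1e-12)[1L]  # ties -> smaller k
  best_k <- k_range[best_idx]
  if (avg[best_idx] <= 1 / best_k + 0.1) {
    message(sprintf(
      "weak cluster structure: best average membership %.3f at k = %d",
      avg[best_idx], best_k))
  }
  structure(list(
    candidate_ks = k_range,
    avg_membership_by_k = avg,
    best_k = best_k,
    model = models[[best_idx]],
    models = models,
    outlier_flags = flag_outliers(models[[best_idx]]$memberships, floor),
    floor = floor
  ), class = "fcm_selection")
}

#' @export
print.fcm_selection <- function(x, ...) {
  cat("Cluster-count selection by average maximum membership\n")
  tab <- data.frame(k = x$candidate_ks,
                    avg_membership = round(x$avg_membership_by_k, 4))
  rownames(tab) <- NULL
  print(tab)
  cat(sprintf("best k = %d; %d subject(s) below the %.2f membership floor\n",
              x$best_k, sum(x$outlier_flags), x$floor))
  invisible(x)
}

#' Relabel clusters in ascending order of mean Cobb angle
#'
#' Reporting convention: cluster 1 holds the mildest coronal deformity and
#' cluster k the most severe, measured by the mean raw major-curve Cobb angle
#' of non-outlier members (argmax assignment). Centroid rows and membership
#' columns are permuted consistently. Relabeling is idempotent; exact ties in
#' mean Cobb keep the lower original index first (logged).
#'
#' @param model An `"fcm"` fit.
#' @param cobb Raw Cobb angles (degrees) aligned with the model's rows.
#' @param outlier Logical outlier flags aligned with rows; flagged subjects
#'   are ignored when ranking clusters. Default: none.
#' @return The relabeled `"fcm"` model, with attribute `label_map` giving
#'   `new_label[old_label]` and `cluster_mean_cobb` in the new order. An
#'   empty cluster (no non-outlier members) ranks by its centroid's raw Cobb.
#' @export
canonical_order <- function(model, cobb, outlier = NULL) {
  stopifnot(inherits(model, "fcm"))
  u <- model$memberships
  n <- nrow(u)
  stopifnot(is.numeric(cobb), length(cobb) == n)
  if (is.null(outlier)) outlier <- rep(FALSE, n)
  hard <- hard_assignments(u)
  mean_cobb <- vapply(seq_len(model$k), function(j) {
    member <- hard == j & !outlier
    if (any(member)) mean(cobb[member])
    else if (!is.null(model$centroids_raw)) model$centroids_raw[j, "cobb_major"]
    else Inf
  }, numeric(1))
  if (anyDuplicated(mean_cobb)) {
    message("tie in mean Cobb angle; lower original cluster index kept first")
  }
  perm <- order(mean_cobb)            # perm[new] = old; stable for ties
  label_map <- order(perm)            # label_map[old] = new
  model$centroids <- model$centroids[perm, , drop = FALSE]
  if (!is.null(model$centroids_raw)) {
    model$centroids_raw <- model$centroids_raw[perm, , drop = FALSE]
  }
  model$memberships <- model$memberships[, perm, drop = FALSE]
  attr(model, "label_map") <- label_map
  attr(model, "cluster_mean_cobb") <- mean_cobb[perm]
  model
}
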