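# Cluster comparison: one-way ANOVA per clinical index and Tukey HSD
# post-hoc pairwise tests (Tukey-Kramer for unequal group sizes).

as_group_list <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- as.character(seq_along(groups))
  }
  small <- vapply(groups, length, integer(1)) < 2L
  if (any(small)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(groups)[small], collapse = ", "))
  }
  groups
}

#' One-way ANOVA across clusters
#'
#' Classic between/within decomposition, `F = MS_between / MS_within`, with
#' the p-value from the upper tail of the F distribution on (k - 1, N - k)
#' degrees of freedom (fit via [stats::lm()]). When the within-group variance
#' is exactly zero but group means differ, the p-value is reported as 0 with
#' a warning.
#'
#' @param groups List of numeric vectors, one per cluster, each with at least
#'   2 observations; names become cluster labels.
#' @param index_name Optional label for the clinical index being compared.
#' @return List of class `"eos_anova"`: `index_name`, `f_stat`, `p_value`,
#'   `df_between`, `df_within`, `group_means`, `group_sds`, `group_ns`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))  # F = 13.5
#' @export
one_way_anova <- function(groups, index_name = NA_character_) {
  groups <- as_group_list(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  k <- length(groups)
  N <- length(y)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ssw < .Machine$double.eps * sum(y^2 + 1)) {
    means <- vapply(groups, mean, numeric(1))
    if (max(means) - min(means) > 0) {
      warning("zero within-group variance with differing means; p set to 0")
      f <- Inf
      p <- 0
    } else {
      f <- 0
      p <- 1
    }
  } else {
    tab <- stats::anova(stats::lm(y ~ g))
    f <- tab[["F value"]][1L]
    p <- tab[["Pr(>F)"]][1L]
  }
  structure(list(
    index_name = index_name,
    f_stat = f, p_value = p,
    df_between = k - 1L, df_within = N - k,
    group_means = vapply(groups, mean, numeric(1)),
    group_sds = vapply(groups, stats::sd, numeric(1)),
    group_ns = vapply(groups, length, integer(1))
  ), class = "eos_anova")
}

#' @export
print.eos_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA%s: F(%d, %d) = %.4g, p = %.3g\n",
              if (is.na(x$index_name)) "" else paste0(" [", x$index_name, "]"),
              x$df_between, x$df_within, x$f_stat, x$p_value))
  invisible(x)
}

#' Tukey HSD post-hoc pairwise comparisons
#'
#' All-pairs comparison of group means using the studentized range
#' distribution (via [stats::TukeyHSD()]); unequal group sizes are handled by
#' the Tukey-Kramer harmonic form. Significance is judged on the adjusted
#' p-value at `alpha`.
#'
#' @inheritParams one_way_anova
#' @param alpha Family-wise significance level. Default 0.01.
#' @return List of class `"eos_tukey"`: `index_name`, `alpha`, and `pairs`, a
#'   data frame with one row per unordered pair (`cluster_a`, `cluster_b`,
#'   `mean_diff` = mean(b) - mean(a), `adjusted_p`, `significant`).
#' @export
tukey_hsd <- function(groups, alpha = 0.01, index_name = NA_character_) {
  groups <- as_group_list(groups)
  stopifnot(alpha > 0, alpha < 1)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  labs <- names(groups)
  combos <- utils::combn(length(labs), 2L)
  if (ssw < .Machine$double.eps * sum(y^2 + 1)) {
    means <- vapply(groups, mean, numeric(1))
    warning("zero within-group variance; pairwise p set to 0 or 1 exactly")
    pairs <- data.frame(
      cluster_a = labs[combos[1L, ]],
      cluster_b = labs[combos[2L, ]],
      mean_diff = means[combos[2L, ]] - means[combos[1L, ]],
      adjusted_p = ifelse(means[combos[2L, ]] != means[combos[1L, ]], 0, 1),
      stringsAsFactors = FALSE)
  } else {
    tk <- stats::TukeyHSD(stats::aov(y ~ g), conf.level = 1 - alpha)$g
    # TukeyHSD rows are "b-a"; rebuild in combn order for a stable contract
    key <- paste(labs[combos[2L, ]], labs[combos[1L, ]], sep = "-")
    tk <- tk[key, , drop = FALSE]
    pairs <- data.frame(
      cluster_a = labs[combos[1L, ]],
      cluster_b = labs[combos[2L, ]],
      mean_diff = unname(tk[, "diff"]),
      adjusted_p = unname(tk[, "p adj"]),
      stringsAsFactors = FALSE)
  }
  pairs$significant <- pairs$adjusted_p < alpha
  structure(list(index_name = index_name, alpha = alpha, pairs = pairs),
            class = "eos_tukey")
}

#' @export
print.eos_tukey <- function(x, ...) {
  cat(sprintf("Tukey HSD%s (alpha = %g):\n",
              if (is.na(x$index_name)) "" else paste0(" [", x$index_name, "]"),
              x$alpha))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' ANOVA and Tukey HSD for every clinical index across clusters
#'
#' Convenience wrapper used by the pipeline: splits each column of a raw-unit
#' feature matrix by cluster label (outlier-flagged subjects excluded, as
#' they are excluded from cluster membership) and runs [one_way_anova()] and
#' [tukey_hsd()] per index.
#'
#' @param x Raw-unit feature matrix (n x 6) as from [build_feature_matrix()].
#' @param cluster Integer cluster labels aligned with rows.
#' @param outlier Logical flags; flagged rows are dropped. Default none.
#' @param alpha Significance level for Tukey HSD. Default 0.01.
#' @return List with `anova` and `tukey`, each a named list over the six
#'   features.
#' @export
compare_clusters <- function(x, cluster, outlier = NULL, alpha = 0.01) {
  stopifnot(is.matrix(x), length(cluster) == nrow(x))
  if (is.null(outlier)) outlier <- rep(FALSE, nrow(x))
  keep <- !outlier
  cl <- cluster[keep]
  feats <- colnames(x)
  anova <- list()
  tukey <- list()
  for (f in feats) {
    groups <- split(x[keep, f], cl)
    anova[[f]] <- one_way_anova(groups, index_name = f)
    tukey[[f]] <- tukey_hsd(groups, alpha = alpha, index_name = f)
  }
  list(anova = anova, tukey = tukey)
}
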