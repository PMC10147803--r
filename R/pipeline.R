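# End-to-end analysis per etiology: features -> standardize -> select k ->
# outlier flags -> canonical ordering -> summaries -> ANOVA/Tukey; plus
# frozen-model scoring of new patients and JSON/CSV export.

#' Analysis configuration
#'
#' Assembles (and validates) the run configuration. Every run embeds the
#' resolved configuration in its output for provenance; a run is fully
#' reproducible from (input table, config).
#'
#' @param seed Integer seed driving all randomness (fuzzy C-means starts).
#' @param m Fuzzifier, > 1. Default 2.
#' @param tol Convergence tolerance on memberships. Default 1e-6.
#' @param max_iter Iteration cap per start. Default 300.
#' @param n_starts Random restarts per fit. Default 10.
#' @param k_range Candidate cluster counts. Default 2:6.
#' @param membership_floor Outlier floor in (0, 1). Default 0.6.
#' @param alpha Significance level for ANOVA/Tukey reporting. Default 0.01.
#' @param refit_after_exclusion Refit the winning model on the non-outlier
#'   subset before reporting? Default `FALSE` (assignments are frozen at fit
#'   time; outlier flags are never revised by the refit).
#' @param deformity_floor Kyphosis floor (degrees) for the deformity index.
#'   Default 1.
#' @return A list of class `"act_config"`.
#' @export
act_config <- function(seed = 1, m = 2, tol = 1e-6, max_iter = 300,
                       n_starts = 10, k_range = 2:6, membership_floor = 0.6,
                       alpha = 0.01, refit_after_exclusion = FALSE,
                       deformity_floor = 1) {
  stopifnot(m > 1, tol > 0, max_iter >= 1, n_starts >= 1,
            all(k_range >= 2), membership_floor > 0, membership_floor < 1,
            alpha > 0, alpha < 1, is.logical(refit_after_exclusion),
            deformity_floor > 0)
  structure(list(seed = as.integer(seed), m = m, tol = tol,
                 max_iter = as.integer(max_iter),
                 n_starts = as.integer(n_starts),
                 k_range = as.integer(sort(unique(k_range))),
                 membership_floor = membership_floor, alpha = alpha,
                 refit_after_exclusion = isTRUE(refit_after_exclusion),
                 deformity_floor = deformity_floor),
            class = "act_config")
}

#' Read an analysis configuration from JSON
#'
#' Unknown keys are rejected; missing keys take the [act_config()] defaults.
#'
#' @param path Path to a JSON object of configuration fields.
#' @return An `"act_config"` list.
#' @export
read_act_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(act_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(act_config, cfg)
}

analyze_etiology <- function(records, config) {
  eti <- unique(records$etiology)
  n_eligible <- nrow(records)
  fm <- build_feature_matrix(records, deformity_floor = config$deformity_floor)
  n_excluded_missing <- n_eligible - nrow(fm)
  if (nrow(fm) < max(config$k_range) + 1L) {
    return(structure(list(etiology = eti, skipped = TRUE,
                          reason = sprintf(
                            "only %d complete record(s); need at least %d",
                            nrow(fm), max(config$k_range) + 1L)),
                     class = "eos_etiology_result"))
  }
  z <- standardize(fm)
  sel <- select_k(z, k_range = config$k_range, m = config$m, tol = config$tol,
                  max_iter = config$max_iter, n_starts = config$n_starts,
                  seed = config$seed, floor = config$membership_floor)
  outlier <- sel$outlier_flags
  model <- sel$model
  if (config$refit_after_exclusion && any(outlier) && !all(outlier)) {
    z_keep <- unclass(z)[!outlier, , drop = FALSE]
    refit <- fcm(z_keep, k = sel$best_k, m = config$m, tol = config$tol,
                 max_iter = config$max_iter, n_starts = config$n_starts,
                 seed = config$seed)
    refit$scaling <- attr(z, "scaling")
    refit$centroids_raw <- destandardize(refit$centroids, refit$scaling)
    # re-evaluate everyone against the refit centroids; flags stay frozen
    refit$memberships <- update_memberships(unclass(z), refit$centroids,
                                            config$m)
    refit$subject_ids <- attr(z, "subject_ids")
    refit$etiology <- eti
    refit$n <- nrow(z)
    model <- refit
  }
  cobb <- unclass(fm)[, "cobb_major"]
  model <- canonical_order(model, cobb = cobb, outlier = outlier)
  u <- model$memberships
  cluster <- hard_assignments(u)
  assignments <- data.frame(
    subject_id = attr(fm, "subject_ids"),
    cluster = cluster,
    max_membership = apply(u, 1L, max),
    outlier = outlier,
    stringsAsFactors = FALSE)
  summary_table <- cluster_summary_table(unclass(fm), cluster, outlier)
  stats <- compare_clusters(unclass(fm), cluster, outlier,
                            alpha = config$alpha)
  scatter <- data.frame(
    cobb_major_deg = unclass(fm)[, "cobb_major"],
    kyphosis_deg = unclass(fm)[, "kyphosis"],
    cluster = ifelse(outlier, "outlier", as.character(cluster)),
    stringsAsFactors = FALSE)
  structure(list(
    etiology = eti, skipped = FALSE,
    n_eligible = n_eligible,
    n_excluded_missing = n_excluded_missing,
    n_outliers = sum(outlier),
    n_included = nrow(fm) - sum(outlier),
    excluded = attr(fm, "excluded"),
    selection = sel,
    model = model,
    assignments = assignments,
    summary_table = summary_table,
    anova = stats$anova,
    tukey = stats$tukey,
    scatter_export = scatter
  ), class = "eos_etiology_result")
}

# Per-cluster mean +/- SD of every raw index over non-outlier subjects,
# rows in canonical (ascending-Cobb) label order.
cluster_summary_table <- function(x, cluster, outlier) {
  keep <- !outlier
  labs <- sort(unique(cluster[keep]))
  rows <- lapply(labs, function(j) {
    sub <- x[keep & cluster == j, , drop = FALSE]
    row <- list(cluster = j, n = nrow(sub))
    for (f in colnames(x)) {
      row[[paste0(f, "_mean")]] <- mean(sub[, f])
      row[[paste0(f, "_sd")]] <- stats::sd(sub[, f])
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the automated clustering analysis for every etiology
#'
#' For each etiology present in `records`: build the six-feature matrix
#' (excluding records with missing indices), standardize, select the cluster
#' count by average membership over `config$k_range`, flag subjects below the
#' membership floor as outliers, relabel clusters in ascending order of mean
#' Cobb angle, then summarize and compare clusters index-by-index with
#' one-way ANOVA and Tukey HSD. Etiologies with fewer complete records than
#' `max(k_range) + 1` are reported as skipped. The full run is reproducible
#' from (input table, config).
#'
#' @param records Patient data frame in the canonical schema (one or more
#'   etiologies), e.g. from [read_patients()] or [generate_cohort()].
#' @param config An [act_config()].
#' @param etiologies Which etiologies to analyze; default all present.
#' @return Object of class `"act_analysis"`: list with `results` (named list
#'   of `"eos_etiology_result"`), and the resolved `config`.
#' @seealso [score_patients()], [write_act_results()]
#' @export
run_act <- function(records, config = act_config(),
                    etiologies = intersect(EOS_ETIOLOGIES,
                                           unique(records$etiology))) {
  stopifnot(inherits(config, "act_config"), is.data.frame(records))
  etiologies <- match.arg(etiologies, EOS_ETIOLOGIES, several.ok = TRUE)
  results <- list()
  for (eti in etiologies) {
    sub <- records[!is.na(records$etiology) & records$etiology == eti, ,
                   drop = FALSE]
    if (nrow(sub) == 0L) {
      results[[eti]] <- structure(
        list(etiology = eti, skipped = TRUE, reason = "no records"),
        class = "eos_etiology_result")
    } else {
      results[[eti]] <- analyze_etiology(sub, config)
    }
  }
  structure(list(results = results, config = config), class = "act_analysis")
}

#' @export
print.eos_etiology_result <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat(sprintf("%s: skipped (%s)\n", x$etiology, x$reason))
    return(invisible(x))
  }
  cat(sprintf("%s: k = %d clusters (avg membership %.3f)\n", x$etiology,
              x$selection$best_k,
              max(x$selection$avg_membership_by_k)))
  cat(sprintf("  subjects: %d eligible, %d excluded (missing), %d outliers (< %.2f), %d included\n",
              x$n_eligible, x$n_excluded_missing, x$n_outliers,
              x$selection$floor, x$n_included))
  cat("  cluster sizes:",
      paste(x$summary_table$n, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.act_analysis <- function(x, ...) {
  cat("Automated EOS clustering analysis\n")
  for (r in x$results) print(r)
  invisible(x)
}

#' @export
summary.act_analysis <- function(object, ...) {
  done <- Filter(function(r) !isTRUE(r$skipped), object$results)
  tab <- do.call(rbind, lapply(done, function(r) {
    data.frame(etiology = r$etiology, best_k = r$selection$best_k,
               avg_membership = max(r$selection$avg_membership_by_k),
               n_eligible = r$n_eligible, n_outliers = r$n_outliers,
               n_included = r$n_included, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  tab
}

#' Kyphosis versus Cobb scatter of the fitted clusters
#'
#' The standard visualization of an etiology's clusters: one point per
#' subject in the kyphosis-Cobb plane, colored by canonical cluster label;
#' membership-floor outliers are drawn as grey crosses.
#'
#' @param x An `"eos_etiology_result"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.eos_etiology_result <- function(x, ...) {
  if (isTRUE(x$skipped)) stop("etiology was skipped: ", x$reason)
  s <- x$scatter_export
  out <- s$cluster == "outlier"
  k <- x$selection$best_k
  pal <- grDevices::hcl.colors(k, "Dark 3")
  col <- ifelse(out, "grey50", pal[suppressWarnings(as.integer(s$cluster))])
  pch <- ifelse(out, 4L, 19L)
  graphics::plot(s$cobb_major_deg, s$kyphosis_deg, col = col, pch = pch,
                 xlab = "Major curve (Cobb) angle [deg]",
                 ylab = "Kyphosis [deg]",
                 main = sprintf("%s (k = %d)", x$etiology, k), ...)
  graphics::legend("topleft", bty = "n",
                   legend = c(paste("cluster", seq_len(k)), "outlier"),
                   col = c(pal, "grey50"), pch = c(rep(19L, k), 4L))
  invisible(x)
}

#' @export
plot.act_analysis <- function(x, ...) {
  done <- Filter(function(r) !isTRUE(r$skipped), x$results)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(done)))
  on.exit(graphics::par(old))
  for (r in done) plot(r, ...)
  invisible(x)
}

#' Score new patients against a frozen fitted model
#'
#' The per-patient assignment a clinician-facing application performs:
#' standardize the new record with the model's stored scaling, evaluate fuzzy
#' memberships against the frozen (canonically ordered) centroids, label by
#' maximum membership, and flag as outlier below the floor. Never refits;
#' scoring a record alone or in a batch gives identical results.
#'
#' @param model An `"fcm"` fit with stored scaling (e.g. `result$model` from
#'   [run_act()], or [read_fcm_model()]).
#' @param records New patients in the canonical schema; any missing index is
#'   an error naming the field.
#' @param floor Membership floor for the outlier flag. Default 0.6.
#' @param deformity_floor Kyphosis floor (degrees). Default 1.
#' @return Data frame: `subject_id`, `cluster`, `max_membership`, `outlier`,
#'   and one `membership_<j>` column per cluster.
#' @export
score_patients <- function(model, records, floor = 0.6, deformity_floor = 1) {
  stopifnot(inherits(model, "fcm"))
  if (is.null(model$scaling)) stop("model stores no scaling")
  need <- c("age_years", "cobb_major_deg", "kyphosis_deg", "levels_cobb",
            "levels_kyphosis")
  for (f in need) {
    if (is.null(records[[f]]) || anyNA(records[[f]])) {
      stop("missing required field: ", f)
    }
  }
  di <- deformity_index(records$cobb_major_deg, records$kyphosis_deg,
                        floor = deformity_floor)
  x <- cbind(age = records$age_years,
             cobb_major = records$cobb_major_deg,
             kyphosis = records$kyphosis_deg,
             levels_cobb = records$levels_cobb,
             levels_kyphosis = records$levels_kyphosis,
             deformity_index = di)
  pr <- predict(model, newdata = x, raw = TRUE)
  out <- data.frame(
    subject_id = if (is.null(records$subject_id))
      as.character(seq_len(nrow(x))) else as.character(records$subject_id),
    cluster = pr$cluster,
    max_membership = pr$max_membership,
    outlier = pr$max_membership < floor,
    stringsAsFactors = FALSE)
  u <- pr$membership
  colnames(u) <- paste0("membership_", seq_len(ncol(u)))
  cbind(out, as.data.frame(u))
}

#' Serialize a fitted model to JSON
#'
#' Writes everything scoring needs (centroids in standardized and original
#' units, scaling parameters, fuzzifier, k, seed, etiology, feature names) so
#' a model can be reloaded with [read_fcm_model()] and reused without the
#' training data.
#'
#' @param model An `"fcm"` fit with stored scaling.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fcm_model <- function(model, path) {
  stopifnot(inherits(model, "fcm"))
  obj <- list(
    type = "eosclust_fcm_model",
    k = model$k, m = model$m, seed = model$seed,
    etiology = model$etiology,
    features = colnames(model$centroids),
    centroids_std = lapply(seq_len(model$k), function(j)
      as.numeric(model$centroids[j, ])),
    centroids_raw = if (!is.null(model$centroids_raw))
      lapply(seq_len(model$k), function(j)
        as.numeric(model$centroids_raw[j, ])),
    scaling = lapply(model$scaling, as.numeric))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Reload a serialized model for scoring
#'
#' @param path JSON path written by [write_fcm_model()].
#' @return An `"fcm"` object (no memberships; sufficient for
#'   [score_patients()] and [predict.fcm()]).
#' @export
read_fcm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "eosclust_fcm_model")) {
    stop("not an eosclust model file: ", path)
  }
  feats <- obj$features
  cen <- obj$centroids_std
  if (!is.matrix(cen)) cen <- do.call(rbind, lapply(cen, as.numeric))
  colnames(cen) <- feats
  scaling <- list(center = stats::setNames(as.numeric(obj$scaling$center),
                                           feats),
                  scale = stats::setNames(as.numeric(obj$scaling$scale),
                                          feats))
  structure(list(
    k = as.integer(obj$k), m = obj$m,
    centroids = cen,
    centroids_raw = destandardize(cen, scaling),
    memberships = NULL, seed = obj$seed,
    scaling = scaling, etiology = obj$etiology,
    n = NA_integer_
  ), class = "fcm")
}

#' Write all analysis outputs to a directory
#'
#' Per etiology: `<etiology>_result.json` (counts, selection, assignments),
#' `<etiology>_model.json` (reloadable frozen model), `<etiology>_summary.csv`
#' (per-cluster mean/SD table), `<etiology>_stats.csv` (tidy ANOVA + Tukey
#' rows), and `<etiology>_scatter.csv` (kyphosis-vs-Cobb plot data). Also
#' `config.json` with the resolved run configuration. Reruns with identical
#' inputs produce byte-identical files.
#'
#' @param analysis An `"act_analysis"` from [run_act()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_act_results <- function(analysis, dir) {
  stopifnot(inherits(analysis, "act_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(analysis$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (r in analysis$results) {
    if (isTRUE(r$skipped)) {
      jsonlite::write_json(list(etiology = r$etiology, skipped = TRUE,
                                reason = r$reason),
                           file.path(dir, paste0(r$etiology, "_result.json")),
                           auto_unbox = TRUE, pretty = TRUE)
      next
    }
    sel <- r$selection
    res <- list(
      etiology = r$etiology,
      n_eligible = r$n_eligible,
      n_excluded_missing = r$n_excluded_missing,
      n_outliers = r$n_outliers,
      n_included = r$n_included,
      selection = list(
        candidate_ks = sel$candidate_ks,
        avg_membership_by_k = as.list(sel$avg_membership_by_k),
        best_k = sel$best_k,
        membership_floor = sel$floor,
        outlier_subject_ids =
          r$assignments$subject_id[r$assignments$outlier]),
      assignments = r$assignments)
    jsonlite::write_json(res,
                         file.path(dir, paste0(r$etiology, "_result.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_fcm_model(r$model, file.path(dir, paste0(r$etiology,
                                                   "_model.json")))
    utils::write.csv(r$summary_table,
                     file.path(dir, paste0(r$etiology, "_summary.csv")),
                     row.names = FALSE)
    utils::write.csv(tidy_stats(r),
                     file.path(dir, paste0(r$etiology, "_stats.csv")),
                     row.names = FALSE)
    utils::write.csv(r$scatter_export,
                     file.path(dir, paste0(r$etiology, "_scatter.csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

# One tidy row per test: ANOVA rows use comparison = "overall", Tukey rows
# use "a-b" pair labels.
tidy_stats <- function(result) {
  rows <- list()
  for (f in names(result$anova)) {
    a <- result$anova[[f]]
    rows[[length(rows) + 1L]] <- data.frame(
      etiology = result$etiology, index = f, comparison = "overall",
      statistic = a$f_stat, p = a$p_value,
      significant = a$p_value < result$tukey[[f]]$alpha,
      stringsAsFactors = FALSE)
    tk <- result$tukey[[f]]$pairs
    rows[[length(rows) + 1L]] <- data.frame(
      etiology = result$etiology, index = f,
      comparison = paste(tk$cluster_a, tk$cluster_b, sep = "-"),
      statistic = tk$mean_diff, p = tk$adjusted_p,
      significant = tk$significant, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
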