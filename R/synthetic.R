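# Synthetic EOS cohort generator: per-etiology finite Gaussian mixtures over
# the five measured indices (the deformity index is always computed, never
# sampled), with valid-range truncation and optional uniform-range outliers.

INDEX_NAMES <- c("age", "cobb_major", "kyphosis", "levels_cobb",
                 "levels_kyphosis")

# Valid ranges used for truncation and for uniform outlier draws.
VALID_RANGES <- list(age = c(0.25, 10), angle = c(10, 150), levels = c(1L, 17L))

# Ranges spec means must respect (clinically plausible cluster centers).
MEAN_RANGES <- list(age = c(0.5, 10), cobb = c(15, 140), kyphosis = c(5, 120),
                    levels = c(3, 14))

#' Describe one mixture component of a synthetic cohort
#'
#' @param weight Mixing weight in (0, 1].
#' @param mean Length-5 numeric vector of component means in index order:
#'   age (years), major curve Cobb angle (degrees), kyphosis (degrees),
#'   levels in the major curve, levels in kyphosis. Must lie within
#'   clinically plausible ranges (age 0.5-10, Cobb 15-140, kyphosis 5-120,
#'   levels 3-14).
#' @param sd Length-5 vector of positive spreads (same order). Indices are
#'   sampled independently (diagonal covariance) unless `cov` is given.
#' @param cov Optional 5 x 5 covariance matrix overriding `sd` for stress
#'   tests with correlated indices.
#' @return A list of class `"cluster_spec"`.
#' @export
cluster_spec <- function(weight, mean, sd, cov = NULL) {
  stopifnot(is.numeric(weight), length(weight) == 1L, weight > 0, weight <= 1,
            is.numeric(mean), length(mean) == 5L,
            is.numeric(sd), length(sd) == 5L, all(sd > 0))
  names(mean) <- names(sd) <- INDEX_NAMES
  ok <- mean["age"] >= MEAN_RANGES$age[1] && mean["age"] <= MEAN_RANGES$age[2] &&
    mean["cobb_major"] >= MEAN_RANGES$cobb[1] &&
    mean["cobb_major"] <= MEAN_RANGES$cobb[2] &&
    mean["kyphosis"] >= MEAN_RANGES$kyphosis[1] &&
    mean["kyphosis"] <= MEAN_RANGES$kyphosis[2] &&
    all(mean[4:5] >= MEAN_RANGES$levels[1]) &&
    all(mean[4:5] <= MEAN_RANGES$levels[2])
  if (!ok) stop("cluster means outside clinically plausible ranges")
  if (!is.null(cov)) {
    stopifnot(is.matrix(cov), all(dim(cov) == 5L))
  }
  structure(list(weight = weight, mean = mean, sd = sd, cov = cov),
            class = "cluster_spec")
}

#' Describe a synthetic per-etiology cohort
#'
#' @param etiology One of `"congenital"`, `"idiopathic"`, `"neuromuscular"`,
#'   `"syndromic"`.
#' @param n_subjects Cohort size; at least 10 subjects per mixture component.
#' @param clusters List of [cluster_spec()] components; mixing weights must
#'   sum to 1 (tolerance 1e-9).
#' @param outlier_fraction Fraction of subjects replaced by uniform draws
#'   over the full valid ranges, in \[0, 0.2\]. Exactly
#'   `round(outlier_fraction * n_subjects)` subjects are injected.
#' @param missing_rate Fraction of subjects that lose one randomly chosen
#'   index (set to `NA`), in \[0, 0.5\]. Default 0.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(etiology, n_subjects, clusters,
                        outlier_fraction = 0, missing_rate = 0, seed = 1) {
  etiology <- match.arg(etiology, EOS_ETIOLOGIES)
  stopifnot(is.list(clusters), length(clusters) >= 1L,
            all(vapply(clusters, inherits, logical(1), "cluster_spec")),
            n_subjects >= 10L * length(clusters),
            outlier_fraction >= 0, outlier_fraction <= 0.2,
            missing_rate >= 0, missing_rate <= 0.5)
  w <- vapply(clusters, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) {
    stop(sprintf("mixing weights must sum to 1 (got %.12f)", sum(w)))
  }
  structure(list(etiology = etiology, n_subjects = as.integer(n_subjects),
                 clusters = clusters, outlier_fraction = outlier_fraction,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Built-in synthetic cohort specifications, one per etiology
#'
#' Loads the versioned mixture parameters shipped in
#' `extdata/default_cohort_specs.json`: three well-separated components per
#' etiology ordered by ascending mean Cobb angle. The neuromuscular and
#' syndromic cohorts each contain exactly one kyphosis-dominant component
#' (mean kyphosis above mean Cobb, so its expected deformity index is below
#' 1); every congenital and idiopathic component has mean Cobb at or above
#' mean kyphosis. These are plausible synthetic magnitudes, not estimates of
#' any registry cohort.
#'
#' @param n_subjects Subjects per etiology. Default 250.
#' @param outlier_fraction Injected outlier fraction per cohort. Default 0.05.
#' @param seed Base seed; etiology i uses `seed + i - 1`.
#' @return Named list of [cohort_spec()] objects keyed by etiology.
#' @export
default_cohort_specs <- function(n_subjects = 250, outlier_fraction = 0.05,
                                 seed = 1) {
  path <- system.file("extdata", "default_cohort_specs.json",
                      package = "eosclust", mustWork = TRUE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(seq_along(EOS_ETIOLOGIES), function(i) {
    eti <- EOS_ETIOLOGIES[i]
    cl <- cfg$etiologies[[eti]]$clusters
    comps <- lapply(seq_len(nrow(cl)), function(j) {
      cluster_spec(weight = cl$weight[j],
                   mean = unlist(cl$mean[j]),
                   sd = unlist(cl$sd[j]))
    })
    cohort_spec(etiology = eti, n_subjects = n_subjects, clusters = comps,
                outlier_fraction = outlier_fraction,
                seed = as.integer(seed) + i - 1L)
  })
  names(out) <- EOS_ETIOLOGIES
  out
}

# Draw n values from one component for all five indices, truncating to the
# valid ranges: age clipped to [0.25, 10], angles to [10, 150], level counts
# rounded to integers in [1, 17].
draw_component <- function(spec, n) {
  if (!is.null(spec$cov)) {
    z <- matrix(stats::rnorm(n * 5L), n, 5L) %*% chol(spec$cov)
    x <- sweep(z, 2L, spec$mean, "+")
  } else {
    x <- sapply(seq_len(5L), function(j) {
      stats::rnorm(n, spec$mean[j], spec$sd[j])
    })
    if (n == 1L) x <- matrix(x, nrow = 1L)
  }
  colnames(x) <- INDEX_NAMES
  x[, "age"] <- pmin(pmax(x[, "age"], VALID_RANGES$age[1]),
                     VALID_RANGES$age[2])
  for (a in c("cobb_major", "kyphosis")) {
    x[, a] <- pmin(pmax(x[, a], VALID_RANGES$angle[1]),
                   VALID_RANGES$angle[2])
  }
  for (l in c("levels_cobb", "levels_kyphosis")) {
    x[, l] <- pmin(pmax(round(x[, l]), VALID_RANGES$levels[1]),
                   VALID_RANGES$levels[2])
  }
  x
}

#' Generate a synthetic EOS cohort
#'
#' Each subject is drawn from a weight-sampled mixture component with
#' truncated-normal indices; `round(outlier_fraction * n)` subjects are then
#' replaced by draws uniform over the full valid ranges (age 0.25-10 years,
#' angles 10-150 degrees, level counts 1-17). The deformity index is never
#' sampled: it is computed downstream from the sampled Cobb and kyphosis,
#' exactly as for real data. Deterministic given the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame in the canonical CSV schema (see [read_patients()]),
#'   with attribute `truth`: a data frame of `subject_id`, `true_component`
#'   (`NA` for injected outliers) and `is_outlier`, for recovery tests.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  K <- length(spec$clusters)
  w <- vapply(spec$clusters, `[[`, numeric(1), "weight")
  comp <- sample.int(K, n, replace = TRUE, prob = w)
  x <- matrix(NA_real_, n, 5L, dimnames = list(NULL, INDEX_NAMES))
  for (j in seq_len(K)) {
    idx <- which(comp == j)
    if (length(idx) > 0L) {
      x[idx, ] <- draw_component(spec$clusters[[j]], length(idx))
    }
  }
  is_outlier <- rep(FALSE, n)
  n_out <- round(spec$outlier_fraction * n)
  if (n_out > 0L) {
    pos <- sample.int(n, n_out)
    is_outlier[pos] <- TRUE
    comp[pos] <- NA_integer_
    x[pos, "age"] <- stats::runif(n_out, VALID_RANGES$age[1],
                                  VALID_RANGES$age[2])
    x[pos, "cobb_major"] <- stats::runif(n_out, VALID_RANGES$angle[1],
                                         VALID_RANGES$angle[2])
    x[pos, "kyphosis"] <- stats::runif(n_out, VALID_RANGES$angle[1],
                                       VALID_RANGES$angle[2])
    x[pos, "levels_cobb"] <- sample(VALID_RANGES$levels[1]:
                                      VALID_RANGES$levels[2], n_out,
                                    replace = TRUE)
    x[pos, "levels_kyphosis"] <- sample(VALID_RANGES$levels[1]:
                                          VALID_RANGES$levels[2], n_out,
                                        replace = TRUE)
  }
  records <- data.frame(
    subject_id = sprintf("%s-%04d", substr(spec$etiology, 1L, 3L),
                         seq_len(n)),
    etiology = spec$etiology,
    age_years = x[, "age"],
    cobb_major_deg = x[, "cobb_major"],
    kyphosis_deg = x[, "kyphosis"],
    levels_cobb = as.integer(x[, "levels_cobb"]),
    levels_kyphosis = as.integer(x[, "levels_kyphosis"]),
    stringsAsFactors = FALSE)
  if (spec$missing_rate > 0) {
    n_miss <- round(spec$missing_rate * n)
    who <- sample.int(n, n_miss)
    which_col <- sample(3:7, n_miss, replace = TRUE)  # one measured index
    for (i in seq_len(n_miss)) records[who[i], which_col[i]] <- NA
  }
  attr(records, "truth") <- data.frame(
    subject_id = records$subject_id,
    true_component = comp,
    is_outlier = is_outlier,
    stringsAsFactors = FALSE)
  records
}

#' Write a cohort (and optionally its generative truth) to CSV
#'
#' @param records Cohort data frame from [generate_cohort()] or compatible.
#' @param path Output CSV path (canonical schema).
#' @param truth_path Optional path for the side-car truth CSV
#'   (`subject_id`, `true_component`, `is_outlier`); requires a `truth`
#'   attribute.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path, truth_path = NULL) {
  utils::write.csv(records[, EOS_CSV_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  if (!is.null(truth_path)) {
    truth <- attr(records, "truth")
    if (is.null(truth)) stop("records carry no `truth` attribute")
    utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
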