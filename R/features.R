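#' @keywords internal
"_PACKAGE"

# Fixed feature order used everywhere downstream (columns of the feature
# matrix, centroid columns, summary tables).
EOS_FEATURES <- c("age", "cobb_major", "kyphosis",
                  "levels_cobb", "levels_kyphosis", "deformity_index")

EOS_ETIOLOGIES <- c("congenital", "idiopathic", "neuromuscular", "syndromic")

# Required input CSV columns, in canonical order.
EOS_CSV_COLUMNS <- c("subject_id", "etiology", "age_years", "cobb_major_deg",
                     "kyphosis_deg", "levels_cobb", "levels_kyphosis")

#' Deformity index: ratio of major curve Cobb angle to kyphosis
#'
#' The deformity index summarizes whether a patient's coronal deformity
#' (major curve Cobb angle) dominates the sagittal one (kyphosis). Values
#' above 1 indicate a larger coronal curve. Kyphosis values below `floor`
#' (including hypokyphotic or lordotic patients recorded as zero or negative
#' kyphosis) are floored to `floor` degrees so that the ratio stays finite
#' and positive; a warning reports how many values were floored.
#'
#' @param cobb_major Major curve Cobb angle in degrees, positive. Vectorized.
#' @param kyphosis Kyphosis in degrees. Vectorized; recycled against
#'   `cobb_major` only when scalar.
#' @param floor Minimum kyphosis (degrees) used in the denominator. Default 1.
#' @return Numeric vector `cobb_major / pmax(kyphosis, floor)`.
#' @examples
#' deformity_index(60, 30)           # 2
#' deformity_index(45, 45)           # 1
#' deformity_index(50, 0.2)          # 50, with a warning (denominator floored)
#' @export
deformity_index <- function(cobb_major, kyphosis, floor = 1) {
  stopifnot(is.numeric(cobb_major), is.numeric(kyphosis),
            is.numeric(floor), length(floor) == 1L, floor > 0)
  if (any(cobb_major <= 0, na.rm = TRUE)) {
    stop("cobb_major must be positive")
  }
  n_floored <- sum(kyphosis < floor, na.rm = TRUE)
  if (n_floored > 0L) {
    warning(sprintf(
      "%d kyphosis value(s) below %g degrees; denominator floored to %g",
      n_floored, floor, floor))
  }
  cobb_major / pmax(kyphosis, floor)
}

#' Read a patient table from CSV
#'
#' Expects the canonical schema with header columns `subject_id`, `etiology`,
#' `age_years`, `cobb_major_deg`, `kyphosis_deg`, `levels_cobb`,
#' `levels_kyphosis` (UTF-8, comma-delimited, "." decimal, empty field or
#' `NA` for missing). Extra columns are dropped with a message. Ages outside
#' [0, 10] years and level counts outside [1, 17] draw a warning (early onset
#' scoliosis is defined for children under 10) but records are kept; missing
#' values are handled downstream by [build_feature_matrix()].
#'
#' @param path Path to a CSV file.
#' @return A data frame with the canonical columns, `etiology` as character.
#' @export
read_patients <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  missing_cols <- setdiff(EOS_CSV_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("input CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), EOS_CSV_COLUMNS)
  if (length(extra) > 0L) {
    message("ignoring extra column(s): ", paste(extra, collapse = ", "))
  }
  df <- df[, EOS_CSV_COLUMNS]
  df$subject_id <- as.character(df$subject_id)
  bad_eti <- !is.na(df$etiology) & !(df$etiology %in% EOS_ETIOLOGIES)
  if (any(bad_eti)) {
    stop("unknown etiology value(s): ",
         paste(unique(df$etiology[bad_eti]), collapse = ", "))
  }
  if (any(df$age_years < 0 | df$age_years > 10, na.rm = TRUE)) {
    warning("age_years outside [0, 10]: EOS is defined for children under 10")
  }
  lev <- c(df$levels_cobb, df$levels_kyphosis)
  if (any(lev < 1 | lev > 17 | lev != round(lev), na.rm = TRUE)) {
    warning("level counts should be integers in [1, 17]")
  }
  df
}

#' Build the six-feature matrix for one etiology
#'
#' Assembles the unstandardized n x 6 matrix clustered on: age (years), major
#' curve Cobb angle (degrees), kyphosis (degrees), levels in the major curve,
#' levels in kyphosis, and the deformity index computed from the sampled Cobb
#' and kyphosis via [deformity_index()]. Records with any missing index are
#' excluded (not imputed) and reported in the `excluded` attribute, mirroring
#' how registries drop subjects with missing clinical indices.
#'
#' @param records Data frame in the canonical schema (see [read_patients()]);
#'   all rows must share one etiology.
#' @param deformity_floor Kyphosis floor (degrees) passed to
#'   [deformity_index()].
#' @return A numeric matrix of class `"feature_matrix"` with one row per
#'   retained record (input order preserved), columns in the fixed feature
#'   order, and attributes `subject_ids`, `etiology`, `standardized = FALSE`,
#'   and `excluded` (data frame of subject_id + reason).
#' @export
build_feature_matrix <- function(records, deformity_floor = 1) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  missing_cols <- setdiff(EOS_CSV_COLUMNS, names(records))
  if (length(missing_cols) > 0L) {
    stop("records are missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  eti <- unique(records$etiology[!is.na(records$etiology)])
  if (length(eti) != 1L) {
    stop("all records must share one etiology; found: ",
         paste(eti, collapse = ", "))
  }
  raw <- records[, c("age_years", "cobb_major_deg", "kyphosis_deg",
                     "levels_cobb", "levels_kyphosis")]
  incomplete <- !stats::complete.cases(raw) | is.na(records$etiology)
  excluded <- data.frame(subject_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (any(incomplete)) {
    excluded <- data.frame(
      subject_id = as.character(records$subject_id[incomplete]),
      reason = "missing clinical index",
      stringsAsFactors = FALSE)
    message(sprintf("excluded %d record(s) with missing clinical indices",
                    sum(incomplete)))
  }
  keep <- records[!incomplete, , drop = FALSE]
  if (nrow(keep) == 0L) stop("no complete records left after exclusions")
  di <- deformity_index(keep$cobb_major_deg, keep$kyphosis_deg,
                        floor = deformity_floor)
  x <- cbind(age = keep$age_years,
             cobb_major = keep$cobb_major_deg,
             kyphosis = keep$kyphosis_deg,
             levels_cobb = keep$levels_cobb,
             levels_kyphosis = keep$levels_kyphosis,
             deformity_index = di)
  structure(x,
            class = c("feature_matrix", "matrix", "array"),
            subject_ids = as.character(keep$subject_id),
            etiology = eti,
            standardized = FALSE,
            excluded = excluded)
}

#' Standardize a feature matrix (z-scores, scaling retained)
#'
#' The six indices mix incommensurate units (years, degrees, counts, a
#' ratio); without scaling, degree-valued features dominate the Euclidean
#' distances fuzzy C-means uses. Each column is centered and divided by its
#' sample standard deviation (divisor n - 1). Constant columns are mapped to
#' zero with SD recorded as 1 and a warning. The per-column center/scale is
#' stored in the `scaling` attribute so the transform is invertible
#' ([destandardize()]) and reusable when scoring new patients.
#'
#' @param x A `"feature_matrix"` (or plain numeric matrix), n >= 2 rows.
#' @return The standardized matrix with attribute `scaling` (list with
#'   `center` and `scale` vectors) and `standardized = TRUE`. Standardizing an
#'   already standardized matrix is a no-op.
#' @export
standardize <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (isTRUE(attr(x, "standardized"))) return(x)
  if (nrow(x) < 2L) stop("standardization needs at least 2 rows")
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  constant <- scale < .Machine$double.eps^0.5
  if (any(constant)) {
    warning("constant column(s) mapped to 0 with SD recorded as 1: ",
            paste(colnames(x)[constant], collapse = ", "))
    scale[constant] <- 1
  }
  z <- sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
  attributes(z) <- attributes(x)
  attr(z, "standardized") <- TRUE
  attr(z, "scaling") <- list(center = center, scale = scale)
  z
}

#' Invert standardization
#'
#' Maps a standardized matrix (or centroid matrix) back to original units
#' using stored scaling parameters.
#'
#' @param z Standardized matrix.
#' @param scaling List with `center` and `scale`; defaults to the `scaling`
#'   attribute of `z`.
#' @return Matrix in original units.
#' @export
destandardize <- function(z, scaling = attr(z, "scaling")) {
  stopifnot(is.matrix(z), is.list(scaling),
            !is.null(scaling$center), !is.null(scaling$scale))
  z <- unclass(z)
  matrix(sweep(sweep(z, 2L, scaling$scale, "*"), 2L, scaling$center, "+"),
         nrow(z), ncol(z), dimnames = dimnames(z))
}

# Apply a frozen scaling (from a fitted model) to new feature rows.
apply_scaling <- function(x, scaling) {
  sweep(sweep(x, 2L, scaling$center, "-"), 2L, scaling$scale, "/")
}
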