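test_that("deformity index is the Cobb/kyphosis ratio with a floored denominator", {
  expect_identical(deformity_index(60, 30), 2)
  expect_identical(deformity_index(45, 45), 1)
  expect_warning(di <- deformity_index(50, 0.2, floor = 1),
                 "floored")
  expect_identical(di, 50)
  expect_warning(expect_identical(deformity_index(40, -10), 40), "floored")
  expect_error(deformity_index(-5, 30), "positive")
})

test_that("deformity index is scale-consistent above the floor", {
  set.seed(42)
  for (i in 1:25) {
    a <- runif(1, 20, 120)
    b <- runif(1, 5, 100)
    cc <- runif(1, 0.5, 3)
    if (b > 1 && cc * b > 1) {
      expect_equal(deformity_index(cc * a, cc * b), deformity_index(a, b),
                   tolerance = 1e-12)
    }
  }
})

test_that("feature matrix has fixed shape, order, and computed deformity index", {
  recs <- make_records(3)
  fm <- build_feature_matrix(recs)
  expect_identical(dim(unclass(fm)), c(3L, 6L))
  expect_identical(colnames(fm),
                   c("age", "cobb_major", "kyphosis", "levels_cobb",
                     "levels_kyphosis", "deformity_index"))
  expect_identical(attr(fm, "subject_ids"), recs$subject_id)
  expect_equal(unclass(fm)[, "deformity_index"],
               recs$cobb_major_deg / recs$kyphosis_deg,
               ignore_attr = TRUE)

  single <- make_records(1, age = 5, cobb = 80, kyph = 40, lc = 6L, lk = 5L)
  fm1 <- build_feature_matrix(single)
  expect_equal(as.numeric(unclass(fm1)[1, ]), c(5, 80, 40, 6, 5, 2))
})

test_that("records with missing indices are excluded with a logged reason", {
  recs <- make_records(3)
  recs$kyphosis_deg[2] <- NA
  expect_message(fm <- build_feature_matrix(recs), "excluded 1 record")
  expect_identical(nrow(fm), 2L)
  expect_identical(attr(fm, "excluded")$subject_id, "s02")
  expect_identical(attr(fm, "excluded")$reason, "missing clinical index")
  expect_identical(attr(fm, "subject_ids"), c("s01", "s03"))
})

test_that("mixed etiologies are rejected", {
  recs <- make_records(3)
  recs$etiology[2] <- "idiopathic"
  expect_error(build_feature_matrix(recs), "one etiology")
})

test_that("building the matrix is permutation-equivariant", {
  recs <- make_records(8, age = runif(8, 1, 9), cobb = runif(8, 30, 120),
                       kyph = runif(8, 15, 80), lc = sample(3:12, 8, TRUE),
                       lk = sample(3:12, 8, TRUE))
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  fm <- build_feature_matrix(recs)
  fm_p <- build_feature_matrix(recs[perm, ])
  expect_equal(unclass(fm_p), unclass(fm)[perm, ], ignore_attr = TRUE)
  expect_identical(attr(fm_p, "subject_ids"), attr(fm, "subject_ids")[perm])
})

test_that("standardization z-scores with sample SD and stores invertible scaling", {
  x <- matrix(c(1, 2, 3), 3, 1)
  colnames(x) <- "age"
  z <- standardize(x)
  expect_equal(as.numeric(z), c(-1, 0, 1))  # sd((1,2,3)) = 1, divisor n-1

  recs <- make_records(10, age = runif(10, 1, 9), cobb = runif(10, 30, 120),
                       kyph = runif(10, 15, 80), lc = sample(3:12, 10, TRUE),
                       lk = sample(3:12, 10, TRUE))
  fm <- build_feature_matrix(recs)
  z <- standardize(fm)
  expect_true(all(abs(colMeans(unclass(z))) < 1e-9))
  expect_true(all(abs(apply(unclass(z), 2, sd) - 1) < 1e-9))
  back <- destandardize(unclass(z), attr(z, "scaling"))
  expect_equal(back, unclass(fm), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("standardization is idempotent and handles degenerate input", {
  recs <- make_records(6, age = runif(6, 1, 9), cobb = runif(6, 30, 120),
                       kyph = runif(6, 15, 80), lc = sample(3:12, 6, TRUE),
                       lk = sample(3:12, 6, TRUE))
  z <- standardize(build_feature_matrix(recs))
  expect_identical(standardize(z), z)  # no-op on standardized input

  const <- matrix(c(5, 5, 5, 1, 2, 3), 3, 2)
  colnames(const) <- c("a", "b")
  expect_warning(zc <- standardize(const), "constant")
  expect_equal(as.numeric(zc[, 1]), c(0, 0, 0))
  expect_equal(attr(zc, "scaling")$scale[["a"]], 1)

  expect_error(standardize(matrix(1, 1, 2)), "at least 2 rows")
})

test_that("the CSV reader enforces the canonical schema", {
  recs <- make_records(4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(recs, path)
  back <- read_patients(path)
  expect_equal(back, recs, ignore_attr = TRUE)

  recs$extra <- 1
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(recs, path2, row.names = FALSE)
  expect_message(back2 <- read_patients(path2), "extra")
  expect_identical(names(back2),
                   c("subject_id", "etiology", "age_years", "cobb_major_deg",
                     "kyphosis_deg", "levels_cobb", "levels_kyphosis"))

  utils::write.csv(recs[, -3], path2, row.names = FALSE)
  expect_error(read_patients(path2), "missing required column")

  recs3 <- make_records(2)
  recs3$age_years[1] <- 14
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(recs3, path3, row.names = FALSE)
  expect_warning(read_patients(path3), "under 10")
})
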