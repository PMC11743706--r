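# Dataset assembly, min-max normalization and 8:2 splitting.

test_that("normalizer stores column extrema and rejects constant columns", {
  ds <- small_dataset(30)
  params <- fit_normalizer(ds)
  # brute-force column scan oracle
  for (j in 1:10) {
    lo <- Inf; hi <- -Inf
    for (i in seq_len(nrow(ds$X))) {
      lo <- min(lo, ds$X[i, j]); hi <- max(hi, ds$X[i, j])
    }
    expect_identical(unname(params$x_min[j]), lo)
    expect_identical(unname(params$x_max[j]), hi)
  }
  bad <- ds
  bad$X[, 3] <- 42
  expect_error(fit_normalizer(bad), "metatarsal_1")
  const_y <- ds
  const_y$y <- rep(1, length(ds$y))
  expect_error(fit_normalizer(const_y), "target")
})

test_that("normalization maps endpoints to 0/1 and round-trips to 1e-12", {
  ds <- small_dataset(40)
  params <- fit_normalizer(ds)
  Xn <- normalize_features(ds$X, params)
  expect_equal(unname(apply(Xn, 2, min)), rep(0, 10))
  expect_equal(unname(apply(Xn, 2, max)), rep(1, 10))
  set.seed(17)
  X <- matrix(runif(1000 * 10, -50, 250), 1000, 10)
  back <- denormalize_features(normalize_features(X, params), params)
  expect_lt(max(abs(back - X)), 1e-12 * max(abs(X)))
  y <- runif(1000, 100, 900)
  expect_lt(max(abs(denormalize_target(normalize_target(y, params), params) - y)),
            1e-9)
})

test_that("direct worked example of the min-max map", {
  params <- structure(list(x_min = 0, x_max = 10, y_min = 0, y_max = 10),
                      class = "normalization_params")
  expect_equal(drop(normalize_features(matrix(c(0, 5, 10), 3, 1), params)),
               c(0, 0.5, 1))
  expect_equal(normalize_target(c(0, 5, 10), params), c(0, 0.5, 1))
})

test_that("out-of-range values pass through the affine map", {
  params <- structure(list(x_min = 10, x_max = 20, y_min = 0, y_max = 1),
                      class = "normalization_params")
  expect_equal(drop(normalize_features(matrix(c(5, 25), 2, 1), params)),
               c(-0.5, 1.5))
})

test_that("8:2 split partitions 300 rows into 240/60, deterministically", {
  cohort <- generate_cohort(cohort_config(seed = 3))
  ds <- as_dataset(cohort)
  sp <- split_dataset(ds, seed = 42)
  expect_equal(nrow(sp$train$X), 240L)
  expect_equal(nrow(sp$test$X), 60L)
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), seq_len(300L))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  sp2 <- split_dataset(ds, seed = 42)
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- split_dataset(ds, seed = 43)
  expect_false(identical(sp$train_idx, sp3$train_idx))
})

test_that("subject-wise split keeps every subject on one side", {
  cohort <- generate_cohort(cohort_config(seed = 6))
  ds <- as_dataset(cohort)
  sp <- split_dataset(ds, seed = 5, mode = "subject-wise")
  both <- intersect(unique(sp$train$meta$subject_id),
                    unique(sp$test$meta$subject_id))
  expect_length(both, 0)
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), seq_len(300L))
  one_subj <- subset_ds <- structure(list(
    X = ds$X[1:10, ], y = ds$y[1:10],
    meta = data.frame(subject_id = rep("S01", 10))),
    class = "pressure_dataset")
  expect_error(split_dataset(one_subj, mode = "subject-wise"), "2 subjects")
})

test_that("dataset assembly validates and carries metadata", {
  cohort <- generate_cohort(cohort_config(n_subjects = 2, seed = 2))
  ds <- as_dataset(cohort, response = "true")
  expect_equal(ds$y, cohort$stiffness_true)
  expect_identical(colnames(ds$X), plantar_regions())
  expect_equal(nrow(ds$meta), nrow(ds$X))
  broken <- as.data.frame(cohort)
  broken$region_4 <- NULL
  expect_error(as_dataset(broken), "region")
})

test_that("normalizer and split serialize to JSON and back", {
  dir <- withr::local_tempdir()
  ds <- small_dataset(25)
  params <- fit_normalizer(ds)
  pth <- file.path(dir, "norm.json")
  write_normalizer(params, pth)
  back <- read_normalizer(pth)
  expect_equal(unname(back$x_min), unname(params$x_min))
  expect_equal(back$y_max, params$y_max)
  sp <- split_dataset(ds, seed = 7)
  write_split(sp, file.path(dir, "split.json"))
  parsed <- jsonlite::read_json(file.path(dir, "split.json"),
                                simplifyVector = TRUE)
  expect_equal(parsed$train_idx, sp$train_idx)
})
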