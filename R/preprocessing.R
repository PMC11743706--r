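# Dataset assembly, min-max normalization to (0,1) of features and target,
# seeded 8:2 train/test splitting and inverse transforms.

#' Assemble a supervised dataset from a cohort
#'
#' Stacks the ten regional-pressure columns into an `n x 10` feature matrix
#' and pairs it with one stiffness target per row.  Data are stored
#' sample-major (rows are trial/foot samples).
#'
#' @param cohort A `gait_cohort` data frame (or any data frame with
#'   `region_1..region_10` plus a stiffness column).
#' @param response Which stiffness column to use as target: the observed
#'   (noisy) value or the generator's ground truth.
#' @return A `pressure_dataset`: list with `X` (n x 10 matrix, columns named
#'   by region), `y` (length-n numeric, N/m) and `meta` (subject/foot/trial
#'   per row).
#' @export
as_dataset <- function(cohort, response = c("observed", "true")) {
  response <- match.arg(response)
  cols <- paste0("region_", seq_len(N_REGIONS))
  if (!all(cols %in% names(cohort))) {
    stopf("cohort lacks the region_1..region_%d columns", N_REGIONS)
  }
  ycol <- if (response == "observed") "stiffness" else "stiffness_true"
  if (!ycol %in% names(cohort)) stopf("cohort lacks column '%s'", ycol)
  X <- as.matrix(cohort[cols])
  colnames(X) <- plantar_regions()
  y <- as.numeric(cohort[[ycol]])
  if (anyNA(X) || anyNA(y)) stopf("dataset contains missing values")
  if (nrow(X) < 2L) stopf("dataset needs at least 2 samples")
  meta_cols <- intersect(c("subject_id", "foot", "trial"), names(cohort))
  meta <- as.data.frame(cohort[meta_cols], stringsAsFactors = FALSE)
  structure(list(X = X, y = y, meta = meta), class = "pressure_dataset")
}

subset_dataset <- function(dataset, idx) {
  structure(list(X = dataset$X[idx, , drop = FALSE],
                 y = dataset$y[idx],
                 meta = dataset$meta[idx, , drop = FALSE]),
            class = "pressure_dataset")
}

#' Fit min-max normalization parameters
#'
#' Records the per-feature and target minima/maxima of the fitted data, the
#' parameters of the affine map \eqn{x_{std} = (x - x_{min})/(x_{max} -
#' x_{min})} onto (0, 1).  A constant column has no such map and is an
#' error, reported by name.
#'
#' By convention the normalizer is fitted on the full dataset before
#' splitting (features and target alike), matching the pipeline order of
#' normalize-then-split; fit it on a training subset instead if strict
#' train/test separation is wanted.
#'
#' @param dataset A `pressure_dataset`.
#' @return An object of class `normalization_params` with fields `x_min`,
#'   `x_max` (length 10) and `y_min`, `y_max` (scalars).
#' @export
fit_normalizer <- function(dataset) {
  X <- dataset$X
  x_min <- apply(X, 2L, min)
  x_max <- apply(X, 2L, max)
  const <- which(x_max <= x_min)
  if (length(const)) {
    stopf("constant feature column(s): %s (min-max normalization undefined)",
          paste(colnames(X)[const], collapse = ", "))
  }
  y_min <- min(dataset$y)
  y_max <- max(dataset$y)
  if (y_max <= y_min) stopf("constant target column (min-max normalization undefined)")
  structure(list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max),
            class = "normalization_params")
}

#' Apply and invert min-max normalization
#'
#' `normalize_features()`/`normalize_target()` map fitted minima to 0 and
#' maxima to 1; values outside the fitted range pass through the affine map
#' and land outside (0, 1).  `denormalize_features()`/`denormalize_target()`
#' invert the maps exactly.  `normalize_dataset()` returns a dataset with
#' both `X` and `y` normalized.
#'
#' @param X Feature matrix (n x 10) or vector of length 10.
#' @param y Numeric target vector.
#' @param dataset A `pressure_dataset`.
#' @param params A [fit_normalizer()] result.
#' @return Transformed matrix / vector / dataset.
#' @export
normalize_features <- function(X, params) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) != length(params$x_min)) stopf("feature count mismatch")
  sweep(sweep(X, 2L, params$x_min), 2L, params$x_max - params$x_min, `/`)
}

#' @rdname normalize_features
#' @export
denormalize_features <- function(X, params) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  sweep(sweep(X, 2L, params$x_max - params$x_min, `*`), 2L, params$x_min, `+`)
}

#' @rdname normalize_features
#' @export
normalize_target <- function(y, params) {
  (y - params$y_min) / (params$y_max - params$y_min)
}

#' @rdname normalize_features
#' @export
denormalize_target <- function(y, params) {
  y * (params$y_max - params$y_min) + params$y_min
}

#' @rdname normalize_features
#' @export
normalize_dataset <- function(dataset, params) {
  structure(list(X = normalize_features(dataset$X, params),
                 y = normalize_target(dataset$y, params),
                 meta = dataset$meta),
            class = "pressure_dataset")
}

#' Split a dataset into training and test sets
#'
#' Default mode `"trial-random"` permutes rows with the seed and takes the
#' first `round(train_fraction * n)` as training (so trials of one subject
#' can land on both sides -- convenient but leaks subject identity across
#' the split).  Mode `"subject-wise"` keeps all rows of a subject on one
#' side, choosing the subject prefix whose row count is closest to the
#' requested fraction.  Splits are disjoint and exhaustive.
#'
#' @param dataset A `pressure_dataset` with at least 5 rows.
#' @param train_fraction Fraction of rows for training, in (0, 1);
#'   default 0.8.
#' @param seed Integer seed for the permutation.
#' @param mode `"trial-random"` or `"subject-wise"`.
#' @return List with `train` and `test` (`pressure_dataset`s) and the row
#'   indices `train_idx`, `test_idx`; class `dataset_split`.
#' @export
split_dataset <- function(dataset, train_fraction = 0.8, seed = 1L,
                          mode = c("trial-random", "subject-wise")) {
  mode <- match.arg(mode)
  n <- nrow(dataset$X)
  if (n < 5L) stopf("dataset needs at least 5 samples to split")
  check_number(train_fraction, "train_fraction", lower = 0, strict = TRUE)
  if (train_fraction >= 1) stopf("'train_fraction' must be in (0, 1)")
  n_train <- as.integer(round(train_fraction * n))
  n_train <- min(max(n_train, 1L), n - 1L)
  if (mode == "trial-random") {
    perm <- with_seed(seed, sample.int(n))
    train_idx <- sort(perm[seq_len(n_train)])
  } else {
    subj <- dataset$meta$subject_id
    if (is.null(subj) || length(unique(subj)) < 2L) {
      stopf("subject-wise split needs at least 2 subjects")
    }
    subjects <- unique(subj)
    ord <- with_seed(seed, sample(subjects))
    rows_per <- vapply(ord, function(s) sum(subj == s), integer(1))
    cum <- cumsum(rows_per)
    k <- which.min(abs(cum - n_train))
    if (cum[k] >= n) k <- k - 1L  # keep the test side non-empty
    if (k < 1L) stopf("cannot form a non-degenerate subject-wise split")
    train_idx <- which(subj %in% ord[seq_len(k)])
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  structure(list(train = subset_dataset(dataset, train_idx),
                 test = subset_dataset(dataset, test_idx),
                 train_idx = train_idx, test_idx = test_idx,
                 train_fraction = train_fraction, seed = seed, mode = mode),
            class = "dataset_split")
}

#' Persist normalization parameters and split indices to JSON
#'
#' @param params,split Objects to serialize.
#' @param path Output JSON path.
#' @return `path` invisibly; readers return the parsed object.
#' @export
write_normalizer <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_normalizer
#' @export
read_normalizer <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(x_min = as.numeric(p$x_min), x_max = as.numeric(p$x_max),
                 y_min = p$y_min, y_max = p$y_max),
            class = "normalization_params")
}

#' @rdname write_normalizer
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(list(train_idx = split$train_idx,
                            test_idx = split$test_idx,
                            train_fraction = split$train_fraction,
                            seed = split$seed, mode = split$mode),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
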