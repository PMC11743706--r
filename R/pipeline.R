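# End-to-end orchestration: generate -> preprocess -> optimize -> train ->
# evaluate -> explain, with every artifact serialized so a run can be
# reconstructed bit-identically from its manifest.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations.  One global `seed` fans out to
#' deterministic per-stage seeds (cohort generation, splitting, optimizer),
#' so any stage can be re-run standalone and reproduce the full pipeline's
#' output exactly.
#'
#' @param seed Global integer seed.
#' @param cohort A [cohort_config()]; its own seed is overridden by the
#'   fanned-out cohort seed.
#' @param response Target column: observed (noisy) or ground-truth
#'   stiffness.
#' @param train_fraction,split_mode Passed to [split_dataset()].
#' @param arch A [network_architecture()].
#' @param optimizer An [optimizer_config()]; its seed is overridden by the
#'   fanned-out optimizer seed.
#' @param training A [train_config()].
#' @param miv_delta Relative MIV perturbation.
#' @param miv_scope Dataset the MIV is computed on: the full cohort or the
#'   training set only.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            cohort = cohort_config(),
                            response = c("observed", "true"),
                            train_fraction = 0.8,
                            split_mode = c("trial-random", "subject-wise"),
                            arch = network_architecture(),
                            optimizer = optimizer_config(),
                            training = train_config(),
                            miv_delta = 0.1,
                            miv_scope = c("full", "train")) {
  response <- match.arg(response)
  split_mode <- match.arg(split_mode)
  miv_scope <- match.arg(miv_scope)
  seed <- as.integer(seed)
  cohort$seed <- stage_seed(seed, "cohort")
  optimizer$seed <- stage_seed(seed, "optimize")
  structure(list(seed = seed, cohort = cohort, response = response,
                 train_fraction = train_fraction, split_mode = split_mode,
                 arch = arch, optimizer = optimizer, training = training,
                 miv_delta = miv_delta, miv_scope = miv_scope),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys are `seed`, `response`, `train_fraction`,
#' `split_mode`, `miv_delta`, `miv_scope` and the nested sections `cohort`,
#' `arch`, `optimizer`, `training`, each holding arguments of the matching
#' constructor.  Unknown fields are an error naming the field.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("seed", "cohort", "response", "train_fraction", "split_mode",
             "arch", "optimizer", "training", "miv_delta", "miv_scope")
  extra <- setdiff(names(raw), known)
  if (length(extra)) stopf("unknown config field(s): %s",
                           paste(extra, collapse = ", "))
  build <- function(section, constructor) {
    if (is.null(raw[[section]])) return(constructor())
    args <- raw[[section]]
    ok <- names(formals(constructor))
    bad <- setdiff(names(args), ok)
    if (length(bad)) stopf("unknown field(s) in '%s': %s", section,
                           paste(bad, collapse = ", "))
    do.call(constructor, args)
  }
  args <- list(cohort = build("cohort", cohort_config),
               arch = build("arch", network_architecture),
               optimizer = build("optimizer", optimizer_config),
               training = build("training", train_config))
  for (k in c("seed", "response", "train_fraction", "split_mode",
              "miv_delta", "miv_scope")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  do.call(pipeline_config, args)
}

#' Fit the stiffness model on a dataset
#'
#' The modelling core of the pipeline applied to an assembled dataset:
#' fit the normalizer, split 8:2, run the hybrid PSO-GA initializer on the
#' normalized training set, then refine by backpropagation training.
#'
#' @param dataset A `pressure_dataset` (raw scale).
#' @param config A [pipeline_config()] (cohort section unused here).
#' @return List with `model` (a [bp_model()]), `split`, `normalizer`,
#'   `psoga` (the optimizer result) and `training` record.
#' @export
fit_stiffness_model <- function(dataset, config = pipeline_config()) {
  normalizer <- fit_normalizer(dataset)
  split <- split_dataset(dataset, train_fraction = config$train_fraction,
                         seed = stage_seed(config$seed, "split"),
                         mode = config$split_mode)
  train_n <- normalize_dataset(split$train, normalizer)
  psoga <- initialize_network(config$arch, train_n$X, train_n$y,
                              config$optimizer)
  training <- train_bp(psoga$best, config$arch, train_n$X, train_n$y,
                       config$training)
  model <- bp_model(training$genome, config$arch, normalizer,
                    training = training)
  list(model = model, split = split, normalizer = normalizer,
       psoga = psoga, training = training)
}

#' Run the full pipeline and write all artifacts
#'
#' Executes generate, preprocess, optimize, train, evaluate and explain in
#' order and writes the run directory: `cohort.csv` (+ config sidecar),
#' `normalizer.json`, `split.json`, `convergence.csv`, `loss_history.csv`,
#' `model.json`, `error_report.csv`, `miv.csv` and `manifest.json` (config
#' snapshot, seeds, package version, file checksums, timestamp).
#'
#' @param config A [pipeline_config()], or a path to a YAML file for
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `cohort`, `dataset`, `fit` (see
#'   [fit_stiffness_model()]), `report`, `miv` and `dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    stopf("'config' must be a pipeline_config or a YAML path")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  cohort <- stage("generate", generate_cohort(config$cohort))
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  dataset <- stage("preprocess", as_dataset(cohort, response = config$response))
  fit <- stage("fit", fit_stiffness_model(dataset, config))
  write_normalizer(fit$normalizer, file.path(out_dir, "normalizer.json"))
  write_split(fit$split, file.path(out_dir, "split.json"))
  write_convergence_trace(fit$psoga$trace, file.path(out_dir, "convergence.csv"))
  utils::write.csv(data.frame(epoch = seq_along(fit$training$loss_history) - 1L,
                              mse = fit$training$loss_history),
                   file.path(out_dir, "loss_history.csv"), row.names = FALSE)
  write_model(fit$model, file.path(out_dir, "model.json"))
  report <- stage("evaluate", evaluate_sets(fit$model, fit$split))
  write_error_report(report, file.path(out_dir, "error_report.csv"))
  miv_X <- if (config$miv_scope == "full") dataset$X else fit$split$train$X
  miv <- stage("explain", miv_report(fit$model, miv_X, delta = config$miv_delta))
  write_miv_report(miv, file.path(out_dir, "miv.csv"))
  files <- c("cohort.csv", "cohort.csv.config.json", "normalizer.json",
             "split.json", "convergence.csv", "loss_history.csv",
             "model.json", "error_report.csv", "miv.csv")
  manifest <- list(
    package = "plantarstiff",
    version = as.character(utils::packageVersion("plantarstiff")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    stage_seeds = list(cohort = stage_seed(config$seed, "cohort"),
                       split = stage_seed(config$seed, "split"),
                       optimize = stage_seed(config$seed, "optimize")),
    config = serialize_config(config),
    checksums = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(list(cohort = cohort, dataset = dataset, fit = fit,
                 report = report, miv = miv, dir = out_dir))
}

serialize_config <- function(config) {
  out <- lapply(unclass(config), function(x) {
    if (inherits(x, c("cohort_config", "network_architecture",
                      "optimizer_config", "train_config"))) unclass(x) else x
  })
  out
}
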