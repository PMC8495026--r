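# End-to-end orchestration: configuration, reproducible runs and artifact
# output. A run is fully determined by its config + seeds; the manifest
# written alongside the artifacts is sufficient to re-execute it.

#' Build a run configuration
#'
#' @param input Either `"synthetic"` (generate a cohort) or a directory of
#'   WFDB/CSV records plus a metadata CSV.
#' @param n_records Cohort size when `input = "synthetic"`.
#' @param class_mix,separation Synthetic class composition.
#' @param N_values Point counts for the attractor planes.
#' @param r_bins,theta_bins,r_cap Measure-profile binning.
#' @param k First-layer neighbour count.
#' @param n_folds Cross-validation folds.
#' @param stack_size Stacker hidden units.
#' @param seed Master seed for all stochastic steps.
#' @param out_dir Output directory for run artifacts.
#' @param metadata Path to a cohort metadata CSV (non-synthetic input).
#' @param sampling_rate Sampling rate for CSV input records.
#' @param write_features Also write the full feature table (large).
#' @return A `run_config` list.
#' @export
run_config <- function(input = "synthetic", n_records = 60,
                       class_mix = 0.5, separation = 1,
                       N_values = c(3, 5, 7, 9, 11, 13),
                       r_bins = 100, theta_bins = 120, r_cap = 3,
                       k = 20, n_folds = 10, stack_size = 25, seed = 1L,
                       out_dir = "spar_run", metadata = NULL,
                       sampling_rate = 500, write_features = FALSE) {
  cfg <- list(input = input, n_records = n_records, class_mix = class_mix,
              separation = separation, N_values = N_values,
              r_bins = r_bins, theta_bins = theta_bins, r_cap = r_cap,
              k = k, n_folds = n_folds, stack_size = stack_size,
              seed = as.integer(seed), out_dir = out_dir,
              metadata = metadata, sampling_rate = sampling_rate,
              write_features = write_features)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

load_cohort_from_config <- function(config) {
  if (identical(config$input, "synthetic")) {
    return(synthesize_cohort(config$n_records, config$class_mix,
                             seed = config$seed,
                             separation = config$separation))
  }
  if (!dir.exists(config$input))
    stop("input directory not found: ", config$input)
  hea <- list.files(config$input, pattern = "\\.hea$", full.names = TRUE)
  csv <- list.files(config$input, pattern = "\\.csv$", full.names = TRUE)
  if (!is.null(config$metadata) && length(csv))
    csv <- csv[normalizePath(csv) !=
                 normalizePath(config$metadata, mustWork = FALSE)]
  records <- c(
    lapply(hea, read_wfdb_record),
    lapply(csv, read_csv_record, sampling_rate = config$sampling_rate))
  if (!length(records)) stop("no records found under ", config$input)
  cohort <- ecg_cohort(records, provenance = config$input)
  if (!is.null(config$metadata)) {
    md <- read_cohort_metadata(config$metadata)
    for (i in seq_along(cohort$records)) {
      row <- md[md$record_id == cohort$records[[i]]$record_id, ]
      if (nrow(row) == 1) {
        cohort$records[[i]]$sex <- row$sex[1]
        cohort$records[[i]]$age <- as.numeric(row$age[1])
        cohort$records[[i]]$subject_id <- as.character(row$subject_id[1])
        if ("order_key" %in% colnames(row))
          cohort$records[[i]]$order_key <- as.character(row$order_key[1])
      }
    }
  }
  dedupe_first_record(cohort)
}

#' Run the full analysis pipeline
#'
#' Loads or synthesizes the cohort, computes the attractor measure-profile
#' features, assigns stratified folds, runs the nested cross-validated
#' stacked classifier, and writes scores, evaluation report, per-lead
#' accuracy table and a run manifest into `config$out_dir`. Re-running the
#' same config yields identical artifacts.
#'
#' @param config A `run_config`.
#' @param progress Print progress dots during feature extraction.
#' @return Invisibly, a list with `cohort`, `features`, `folds`, `cv` and
#'   the output directory.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (identical(config$input, "synthetic")) {
    if (is.null(config$n_records) || config$n_records < 2)
      stop("config validation: n_records must be >= 2 for synthetic input")
  } else if (!dir.exists(config$input)) {
    stop("config validation: input path does not exist: ", config$input)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- load_cohort_from_config(config)
  planes <- enumerate_planes(config$N_values)
  features <- cohort_features(cohort, planes = planes,
                              r_bins = config$r_bins,
                              theta_bins = config$theta_bins,
                              r_cap = config$r_cap, progress = progress)
  labelled <- features$meta$sex %in% c("female", "male")
  if (!all(labelled)) {
    features$meta <- features$meta[labelled, , drop = FALSE]
    features$features <- lapply(features$features,
                                function(m) m[labelled, , drop = FALSE])
  }
  folds <- stratified_folds(features$meta, n_folds = config$n_folds,
                            seed = config$seed)
  cv <- nested_cross_validate(features, folds, k = config$k,
                              stack_size = config$stack_size,
                              seed = config$seed)
  out <- config$out_dir
  utils::write.csv(cv$scores, file.path(out, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(lead_accuracy_table(cv),
                   file.path(out, "lead_accuracy.csv"), row.names = FALSE)
  utils::write.csv(cv$provenance, file.path(out, "provenance.csv"),
                   row.names = FALSE)
  rep <- cv$report
  jsonlite::write_json(
    list(accuracy = rep$accuracy, auc = rep$auc,
         sensitivity = rep$sensitivity, specificity = rep$specificity,
         confusion = as.list(rep$confusion), n = rep$n),
    file.path(out, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  if (isTRUE(config$write_features))
    utils::write.csv(features_table(features),
                     file.path(out, "features.csv"), row.names = FALSE)
  manifest <- list(
    config = unclass(config),
    n_records = nrow(features$meta),
    n_feature_blocks = length(features$features),
    fold_sizes = folds$fold_sizes,
    package_version = as.character(utils::packageVersion("sparecg")),
    r_version = R.version.string)
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(list(cohort = cohort, features = features, folds = folds,
                 cv = cv, out_dir = out))
}
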