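# Pipeline runner: the subcommand surface behind the command-line script.

#' Run one pipeline subcommand
#'
#' The programmatic equivalent of the `inst/cli/tripleo.R` command-line
#' tool. Each subcommand writes its output tables as headered CSV files
#' into `output_dir`, plus a `run_manifest.yaml` echoing the effective
#' configuration, seed, package version and input checksums.
#'
#' Subcommands:
#' * `simulate` — generate a synthetic cohort (from `sim_args`) and write
#'   its on-disk layout under `output_dir`.
#' * `measures` — score a cohort (`input`) against a reference cohort
#'   (`reference`, defaults to the cohort itself) and write
#'   `measures.csv`.
#' * `classify` — `measures` plus the brain-outlier calls only
#'   (`calls.csv`).
#' * `predict` — Triple O+: measures, CDRI, signed calls
#'   (`predictions.csv`).
#' * `evaluate` — score and evaluate against IQ outcomes; writes
#'   `confusion.csv`, `metrics.csv`, `risk_table.csv` (when demographics
#'   and groups allow) and `summary.txt`.
#' * `sweep` — reference-size resampling from the `reference` pool against
#'   the `input` test cohort; writes `sweep_replicates.csv` and
#'   `sweep_summary.csv`.
#'
#' @param command one of `"simulate"`, `"measures"`, `"classify"`,
#'   `"predict"`, `"evaluate"`, `"sweep"`.
#' @param input cohort directory (or manifest path) of the test cohort.
#' @param reference optional cohort directory of the reference cohort.
#' @param output_dir where outputs are written (created if needed).
#' @param config a `tripleo_config`, a YAML path, or `NULL` for defaults.
#' @param overrides named list of config overrides (highest precedence).
#' @param sim_args named list passed to [sim_params()] for `simulate`.
#' @param scale stored scale of matrix files (see [read_cohort()]).
#' @return invisible list of the paths written.
#' @export
run_pipeline <- function(command = c("simulate", "measures", "classify",
                                     "predict", "evaluate", "sweep"),
                         input = NULL, reference = NULL,
                         output_dir = ".", config = NULL,
                         overrides = list(), sim_args = list(),
                         scale = "fisher_z") {
  command <- match.arg(command)
  cfg <- if (inherits(config, "tripleo_config")) {
    if (length(overrides) > 0L) {
      do.call(read_run_config,
              list(path = NULL,
                   overrides = utils::modifyList(unclass(config), overrides)))
    } else config
  } else {
    read_run_config(config, overrides)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  inputs_used <- character(0)

  load_cohort_arg <- function(path, what) {
    if (is.null(path)) stop(sprintf("subcommand '%s' needs %s", command, what))
    inputs_used <<- c(inputs_used,
                      if (dir.exists(path)) file.path(path, "manifest.csv")
                      else path)
    read_cohort(path, scale = scale)
  }
  emit <- function(df, name) {
    p <- file.path(output_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
    p
  }

  if (command == "simulate") {
    sim_args$seed <- sim_args$seed %||% cfg$seed
    cohort_id <- sim_args$cohort_id %||% 1L
    sim_args$cohort_id <- NULL
    params <- do.call(sim_params, sim_args)
    cohort <- generate_cohort(params, cohort_id = cohort_id)
    manifest <- write_cohort(cohort, output_dir)
    written <- c(written, manifest)
  } else if (command %in% c("measures", "classify", "predict")) {
    test <- load_cohort_arg(input, "an input cohort")
    ref <- if (is.null(reference)) test
           else load_cohort_arg(reference, "a reference cohort")
    ev_measures <- score_against(test, ref, cfg)
    if (command == "measures") {
      emit(ev_measures, "measures.csv")
    } else if (command == "classify") {
      emit(ev_measures[, c("subject_id", "votes", "is_brain_outlier")],
           "calls.csv")
    } else {
      cdri <- compute_cdri(test$subjects, test$subjects,
                           missing_policy = cfg$missing_policy)
      emit(signed_prediction(ev_measures, cdri), "predictions.csv")
    }
  } else if (command == "evaluate") {
    test <- load_cohort_arg(input, "an input cohort")
    ref <- if (is.null(reference)) test
           else load_cohort_arg(reference, "a reference cohort")
    ev <- evaluate_with_reference(
      test, ref,
      iq_threshold = cfg$iq_z, measure_z = cfg$measure_z,
      connection_z = cfg$connection_z, min_votes = cfg$min_votes,
      connection_sidedness = cfg$connection_sidedness,
      self_exclusion = cfg$self_exclusion,
      zero_variance = cfg$zero_variance
    )
    cm <- ev$confusion
    emit(data.frame(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
                    n_total = cm$n_total), "confusion.csv")
    metric_row <- function(name, m) {
      data.frame(stratum = name,
                 sensitivity = m$sensitivity_rounded,
                 specificity = m$specificity_rounded,
                 accuracy = m$accuracy_rounded)
    }
    mt <- metric_row("pooled", ev$metrics)
    if (!is.null(ev$stratified)) {
      for (g in setdiff(names(ev$stratified), "pooled")) {
        mt <- rbind(mt, metric_row(g, ev$stratified[[g]]))
      }
    }
    emit(mt, "metrics.csv")
    if (!is.null(ev$risk_table)) emit(ev$risk_table, "risk_table.csv")
    summary_path <- file.path(output_dir, "summary.txt")
    writeLines(c(
      sprintf("n = %d, tp/fp/fn = %d/%d/%d", cm$n_total, cm$tp, cm$fp,
              cm$fn),
      sprintf("sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%",
              ev$metrics$sensitivity_rounded,
              ev$metrics$specificity_rounded,
              ev$metrics$accuracy_rounded),
      sprintf("Fisher exact p = %.3g", ev$fisher_p)
    ), summary_path)
    written <- c(written, summary_path)
  } else if (command == "sweep") {
    test <- load_cohort_arg(input, "an input (test) cohort")
    pool <- load_cohort_arg(reference, "a reference pool cohort")
    sw <- sweep_reference_size(
      test, pool, sizes = cfg$sizes, n_replicates = cfg$n_replicates,
      seed = cfg$seed,
      iq_threshold = cfg$iq_z, measure_z = cfg$measure_z,
      connection_z = cfg$connection_z, min_votes = cfg$min_votes,
      connection_sidedness = cfg$connection_sidedness,
      self_exclusion = cfg$self_exclusion,
      zero_variance = cfg$zero_variance
    )
    emit(sw$replicates, "sweep_replicates.csv")
    emit(sw$summary, "sweep_summary.csv")
  }

  manifest_path <- file.path(output_dir, "run_manifest.yaml")
  checksums <- if (length(inputs_used) > 0L) {
    sums <- tools::md5sum(inputs_used)
    as.list(stats::setNames(unname(sums), basename(names(sums))))
  } else list()
  yaml::write_yaml(
    list(
      command = command,
      config = unclass(cfg),
      package_version = as.character(utils::packageVersion("tripleo")),
      input_checksums = checksums,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    manifest_path
  )
  written <- c(written, manifest_path)
  invisible(written)
}

# shared scoring path for measures/classify/predict
score_against <- function(test, ref, cfg) {
  if (test$n_regions != ref$n_regions) {
    stop(sprintf("region count mismatch: input %d, reference %d",
                 test$n_regions, ref$n_regions))
  }
  model <- tripleo(
    ref,
    connection_z = cfg$connection_z, measure_z = cfg$measure_z,
    min_votes = cfg$min_votes,
    connection_sidedness = cfg$connection_sidedness,
    self_exclusion = cfg$self_exclusion, zero_variance = cfg$zero_variance
  )
  self_mode <- identical(sort(test$subjects$subject_id),
                         sort(ref$subjects$subject_id))
  if (self_mode) {
    predict(model, test$vectors,
            self_indices = match(test$subjects$subject_id,
                                 rownames(model$reference)))
  } else {
    overlap <- intersect(test$subjects$subject_id, ref$subjects$subject_id)
    if (length(overlap) > 0L) {
      stop(sprintf("input and reference share subject id(s): %s",
                   paste(utils::head(overlap, 3L), collapse = ", ")))
    }
    predict(model, test$vectors)
  }
}
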