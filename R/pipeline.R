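# End-to-end orchestration: simulate a cohort to disk, extract features over
# a manifest, analyze a feature table. Each step serializes its configuration
# (with an md5 provenance hash and the seed) next to its outputs, so a rerun
# with identical config and seed reproduces all declared-deterministic outputs
# bit for bit. The command-line wrapper in `inst/cli/lvadsound.R` is a thin
# shell over these functions.

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

.write_provenance <- function(config, seed, dir, step) {
  obj <- list(step = step, seed = seed, config = config,
              config_hash = .config_hash(config),
              package_version = as.character(utils::packageVersion("lvadsound")))
  jsonlite::write_json(obj, file.path(dir, paste0(step, "_config.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; top-level keys may include `simulate`, `extract`
#'   and `analyze` sections.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  yaml::read_yaml(path)
}

#' Simulate a cohort of recordings to disk
#'
#' Writes one WAV plus one ground-truth JSON sidecar (same basename) per
#' recording, and a cohort manifest CSV with columns `recording_id`, `path`,
#' `ar_label`.
#'
#' @param out_dir output directory (must be empty unless `force`).
#' @param n_recordings,ar_prevalence,duration,effect_multiplier,seed cohort
#'   parameters, see [cohort_spec()].
#' @param force overwrite a non-empty output directory.
#' @param verbose print per-recording progress.
#' @return path of the manifest CSV, invisibly.
#' @export
run_simulate <- function(out_dir, n_recordings = 245,
                         ar_prevalence = 26 / 245, duration = 66,
                         effect_multiplier = 1, seed = 1, force = FALSE,
                         verbose = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop("output directory is not empty (use force = TRUE): ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cohort_spec(n_recordings, ar_prevalence, duration = duration,
                      effect_multiplier = effect_multiplier, seed = seed)
  params <- sample_cohort_params(spec)
  manifest <- data.frame(recording_id = params$recording_id,
                         path = file.path(out_dir,
                                          paste0(params$recording_id, ".wav")),
                         ar_label = params$ar_label,
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(params))) {
    sim <- simulate_cohort(spec, params = params[i, , drop = FALSE])
    write_wav(sim$recordings[[1]], manifest$path[i])
    write_ground_truth(sim$ground_truths[[1]],
                       sub("\\.wav$", ".json", manifest$path[i]))
    if (verbose) message("wrote ", manifest$path[i])
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  .write_provenance(c(unclass(spec)), seed, out_dir, "simulate")
  invisible(file.path(out_dir, "manifest.csv"))
}

#' Extract features for every recording in a manifest
#'
#' Applies [extract_features()] to each WAV listed in a manifest CSV. A
#' recording that fails to analyze produces a row-level failure record (in
#' `<out>_failures.csv`) and the run continues; the feature CSV contains one
#' row per analyzable recording.
#'
#' @param manifest path to a manifest CSV (`recording_id`, `path`,
#'   `ar_label`) or a data.frame.
#' @param out_csv output feature CSV path.
#' @param config a [feature_config()].
#' @param verbose print per-recording timing.
#' @return the [feature_table()] of analyzable recordings, invisibly.
#' @export
run_extract <- function(manifest, out_csv, config = feature_config(),
                        verbose = FALSE) {
  man <- if (is.character(manifest)) utils::read.csv(manifest) else manifest
  rows <- list(); fails <- list()
  for (i in seq_len(nrow(man))) {
    t0 <- Sys.time()
    fv <- tryCatch({
      rec <- suppressWarnings(read_wav(man$path[i],
                                       recording_id = man$recording_id[i]))
      rec$ar_label <- man$ar_label[i]
      suppressWarnings(suppressMessages(extract_features(rec, config)))
    }, error = function(e) e)
    if (inherits(fv, "error")) {
      fails[[length(fails) + 1]] <-
        data.frame(recording_id = man$recording_id[i],
                   error = conditionMessage(fv))
      if (verbose) message(man$recording_id[i], ": FAILED (",
                           conditionMessage(fv), ")")
    } else {
      rows[[length(rows) + 1]] <- as.data.frame(fv)
      if (verbose)
        message(sprintf("%s: %.1f s", man$recording_id[i],
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  if (length(rows) == 0) stop("no recording could be analyzed")
  tab <- feature_table(do.call(rbind, rows))
  write_feature_csv(tab, out_csv)
  if (length(fails) > 0)
    utils::write.csv(do.call(rbind, fails),
                     sub("\\.csv$", "_failures.csv", out_csv),
                     row.names = FALSE)
  invisible(tab)
}

#' Select features and benchmark classifiers on a feature table
#'
#' Draws the stratified 75/25 split first, runs the full selection pipeline
#' (t-test ranking, filter, wrapper) on the training rows only, then
#' benchmarks every classifier on the held-out test rows with the selected
#' subset — so no test-row information reaches ranking, imputation, scaling
#' or tuning.
#'
#' @param features a [feature_table()] or path to a feature CSV.
#' @param out_json optional path for the JSON report (a CSV of the classifier
#'   table is written next to it).
#' @param seed root seed (split, forests, ensemble).
#' @param tune forward to [benchmark_classifiers()].
#' @param ranking ranking driver for the filter stage.
#' @return list with `selection` (a `selection_result`) and `report`
#'   (a `model_report`).
#' @export
run_analyze <- function(features, out_json = NULL, seed = 1, tune = TRUE,
                        ranking = "ttest") {
  tab <- if (is.character(features)) read_feature_csv(features) else features
  stopifnot(inherits(tab, "feature_table"))
  if (!all(tab$ar_label %in% c(0, 1)) || length(unique(tab$ar_label)) < 2)
    stop("analysis requires a binary ar_label column with both classes")
  y <- as.integer(tab$ar_label)
  split <- stratified_split(y, 0.75, seed)
  train_tab <- feature_table(as.data.frame(tab)[split, , drop = FALSE])
  sel <- select_features(train_tab, seed = seed, ranking = ranking)
  subset <- if (length(sel$wrapper_subset) > 0) sel$wrapper_subset
            else sel$filter_subset
  rep <- benchmark_classifiers(tab, subset, split_seed = seed, split = split,
                               tune = tune)
  if (!is.null(out_json)) {
    obj <- list(
      seed = seed,
      split = attr(rep, "split_description"),
      selection = list(driver = sel$driver,
                       ttest_ranking = sel$ttest_ranking,
                       gini_ranking = sel$gini_ranking,
                       filter_trace = sel$filter_trace,
                       filter_subset = sel$filter_subset,
                       wrapper_subset = sel$wrapper_subset),
      classifiers = as.data.frame(rep),
      config_hash = .config_hash(list(seed = seed, tune = tune,
                                      ranking = ranking)))
    jsonlite::write_json(obj, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    utils::write.csv(as.data.frame(rep),
                     sub("\\.json$", "_classifiers.csv", out_json),
                     row.names = FALSE)
  }
  list(selection = sel, report = rep)
}
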