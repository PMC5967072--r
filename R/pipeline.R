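# End-to-end orchestration: simulate (or load) -> fit -> map -> segment ->
# summarize -> correlate, with every intermediate written to disk and a
# provenance record sufficient to regenerate any output.

run_config_fields <- c("mode", "n_patients", "seed", "out_dir",
                       "use_molli_fit", "min_valid_frac", "write_maps",
                       "input_dir", "cohort", "phantom")

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (generate a phantom cohort) or `"files"` (load
#'   patient directories from `input_dir`).
#' @param n_patients cohort size (synthetic mode).
#' @param seed integer seed for all randomness.
#' @param out_dir output directory.
#' @param use_molli_fit refit T1 maps pixelwise from the MOLLI series
#'   (synthetic mode generates the series when this is on).
#' @param min_valid_frac sector exclusion threshold.
#' @param write_maps write per-patient NIfTI maps (and, in synthetic mode,
#'   the full input records).
#' @param input_dir directory of patient subdirectories (files mode), with
#'   a cohort-level `markers.csv`.
#' @param cohort,phantom named lists of [cohort_params()] /
#'   [phantom_params()] overrides; unknown keys are rejected.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"), n_patients = 25,
                       seed = 1L, out_dir = "cmrpet_out",
                       use_molli_fit = TRUE, min_valid_frac = 0.5,
                       write_maps = TRUE, input_dir = NULL,
                       cohort = list(), phantom = list()) {
  cfg <- list(mode = match.arg(mode), n_patients = as.integer(n_patients),
              seed = as.integer(seed), out_dir = out_dir,
              use_molli_fit = isTRUE(use_molli_fit),
              min_valid_frac = min_valid_frac,
              write_maps = isTRUE(write_maps), input_dir = input_dir,
              cohort = cohort, phantom = phantom)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), run_config_fields)
  if (length(unknown))
    user_stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (!cfg$mode %in% c("synthetic", "files"))
    user_stopf("mode must be 'synthetic' or 'files'")
  if (cfg$mode == "files" && is.null(cfg$input_dir))
    user_stopf("files mode requires `input_dir`")
  chk_num(cfg$min_valid_frac, "min_valid_frac", lo = 0, hi = 1)
  if (cfg$mode == "synthetic" && cfg$n_patients < 3)
    user_stopf("n_patients must be >= 3")
  # cohort/phantom overrides are validated by their own constructors
  if (length(cfg$cohort)) do.call(cohort_params, cfg$cohort)
  if (length(cfg$phantom)) do.call(phantom_params, cfg$phantom)
  cfg
}

#' Write / read a run configuration as YAML
#'
#' The configuration round-trips losslessly; unknown keys in the file are
#' rejected with their names.
#'
#' @param config a [run_config()].
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) user_stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), run_config_fields)
  if (length(unknown))
    user_stopf("config %s has unknown key(s): %s", path,
               paste(unknown, collapse = ", "))
  y$mode <- y$mode %||% "synthetic"
  do.call(run_config, y)
}

load_cohort_from_files <- function(input_dir) {
  if (!dir.exists(input_dir)) user_stopf("input directory not found: %s", input_dir)
  dirs <- sort(list.dirs(input_dir, recursive = FALSE))
  dirs <- dirs[file.exists(file.path(dirs, "meta.json"))]
  if (!length(dirs)) user_stopf("no patient directories under %s", input_dir)
  mk_path <- file.path(input_dir, "markers.csv")
  markers <- if (file.exists(mk_path)) read_markers(mk_path) else NULL
  records <- lapply(dirs, function(d) {
    rec <- read_patient_record(d)
    if (!is.null(markers) && rec$id %in% markers$patient) {
      row <- markers[markers$patient == rec$id, ]
      rec$markers <- unlist(row[setdiff(names(row), c("patient", "infarct_size_pct_lv"))])
      rec$truth <- list(infarct_size_pct_lv = row$infarct_size_pct_lv)
    }
    rec
  })
  structure(records, class = "phantom_cohort")
}

stage_context <- function(patient, stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("patient %s, stage %s: %s", patient, stage, conditionMessage(e),
          class = class(e)[1])
  })
}

#' Run the full pipeline
#'
#' Executes the stages in order — simulate or load, T1 fitting (optional),
#' ECV mapping, SUV conversion, sector segmentation, biopsy statistics,
#' correlation analysis — and writes every intermediate: per-patient NIfTI
#' maps, the tidy sector table, biopsy summaries, marker and correlation
#' CSVs, plus `provenance.json` (config hash, seed, package version,
#' excluded-sector counts).  A stage failure aborts with the failing
#' patient and stage named; outputs written so far are retained.
#'
#' Outputs are deterministic for a fixed config and seed (byte-identical
#' CSV/JSON across reruns).
#'
#' @param config a [run_config()] (or path to its YAML file).
#' @return The [analyze_cohort()] result, invisibly, with the output paths
#'   in attribute `"paths"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- validate_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  write_run_config(cfg, cfg_path)

  cohort <- if (cfg$mode == "synthetic") {
    cp_args <- utils::modifyList(cfg$cohort,
                                 list(include_molli = cfg$use_molli_fit,
                                      phantom = cfg$phantom))
    make_cohort(cfg$n_patients, do.call(cohort_params, cp_args),
                seed = cfg$seed)
  } else {
    load_cohort_from_files(cfg$input_dir)
  }

  cache <- new.env(parent = emptyenv())
  per <- lapply(cohort, function(rec)
    stage_context(rec$id, "maps/sectors",
                  process_patient(rec, use_molli_fit = cfg$use_molli_fit,
                                  min_valid_frac = cfg$min_valid_frac,
                                  sector_cache = cache)))

  if (cfg$write_maps) {
    if (cfg$mode == "synthetic") {
      dir.create(file.path(cfg$out_dir, "patients"), recursive = TRUE,
                 showWarnings = FALSE)
      write_markers(cohort_markers(cohort),
                    file.path(cfg$out_dir, "patients", "markers.csv"))
    }
    for (i in seq_along(cohort)) {
      rec <- cohort[[i]]
      pd <- file.path(cfg$out_dir, "patients", rec$id)
      dir.create(pd, recursive = TRUE, showWarnings = FALSE)
      if (cfg$mode == "synthetic")
        stage_context(rec$id, "write-inputs", write_patient_record(rec, pd))
      for (nm in c("native_t1", "post_t1", "ecv", "fdg"))
        write_scalar_map(per[[i]]$maps[[nm]],
                         file.path(pd, sprintf("derived_%s.nii.gz", nm)))
    }
  }

  sectors <- do.call(rbind, lapply(per, `[[`, "sector_table"))
  res <- stage_context("cohort", "statistics", {
    markers <- if (cfg$mode == "synthetic") NULL else {
      mk <- file.path(cfg$input_dir, "markers.csv")
      if (file.exists(mk)) read_markers(mk) else
        data.frame(patient = vapply(cohort, `[[`, "", "id"))
    }
    analyze_precomputed(cohort, per, markers)
  })

  paths <- c(sectors = file.path(cfg$out_dir, "sectors.csv"),
             biopsy = file.path(cfg$out_dir, "biopsy.csv"),
             image_summary = file.path(cfg$out_dir, "image_summary.csv"),
             markers = file.path(cfg$out_dir, "markers.csv"),
             pair_correlations = file.path(cfg$out_dir, "pair_correlations.csv"),
             max_correlations = file.path(cfg$out_dir, "max_correlations.csv"),
             slopes = file.path(cfg$out_dir, "slopes.csv"),
             marker_correlations = file.path(cfg$out_dir, "marker_correlations.csv"),
             distances = file.path(cfg$out_dir, "argmax_distances.csv"))
  for (nm in names(paths))
    utils::write.csv(res[[nm]], paths[nm], row.names = FALSE)

  prov <- list(
    package = "cmrpet",
    version = as.character(utils::packageVersion("cmrpet")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = cfg$seed, mode = cfg$mode,
    n_patients = length(cohort),
    excluded_sectors_per_signal = res$excluded_sectors,
    t1_fit = cfg$use_molli_fit)
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  attr(res, "paths") <- c(paths, config = cfg_path,
                          provenance = file.path(cfg$out_dir, "provenance.json"))
  invisible(res)
}

# assemble a cohort_result from already-processed patients (shared between
# analyze_cohort and run_pipeline so the pipeline does not recompute maps)
analyze_precomputed <- function(cohort, per, markers = NULL) {
  sectors <- do.call(rbind, lapply(per, `[[`, "sector_table"))
  res <- analyze_from_sectors(
    sectors,
    blood_suv = data.frame(
      patient = vapply(cohort, `[[`, "", "id"),
      blood_suv = vapply(per, `[[`, numeric(1), "blood_suv")),
    markers = markers %||% cohort_markers(cohort))
  res
}
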