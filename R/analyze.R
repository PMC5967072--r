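# Cohort analysis: per-patient map derivation (T1 fit or direct maps ->
# ECV, SUV), sector extraction on a cached geometry, biopsy summaries, and
# the full correlation battery.

# derive the per-patient analysis maps; sector maps are cached per
# (n_sectors, geometry) across patients since phantom cohorts share one slice
# geometry
process_patient <- function(record, use_molli_fit = FALSE,
                            min_valid_frac = 0.5, sector_cache = NULL,
                            reference_angle = 0) {
  myo <- record$maps$native_t1$mask
  blood_mask <- record$blood_roi$mask

  if (use_molli_fit) {
    if (is.null(record$molli))
      user_stopf("patient %s has no MOLLI series but use_molli_fit = TRUE", record$id)
    fit_mask <- myo | blood_mask
    t1n <- suppressMessages(fit_t1_map(record$molli$native, fit_mask))
    t1p <- suppressMessages(fit_t1_map(record$molli$post, fit_mask))
    # restrict analysis masks to the myocardium; the cavity pixels only
    # feed the blood-pool statistic
    t1n$mask <- t1n$mask & myo
    t1p$mask <- t1p$mask & myo
  } else {
    t1n <- record$maps$native_t1
    t1p <- record$maps$post_t1
  }

  blood <- blood_pool_sample(t1n, t1p, blood_mask)
  ecv <- suppressMessages(compute_ecv_map(t1n, t1p, blood, record$hct))
  suv <- suv_map(record$maps$pet_activity, record$dose)
  blood_suv <- stats::median(suv$data[blood_mask], na.rm = TRUE)

  key <- sprintf("s%d", record$n_sectors)
  sectors <- if (!is.null(sector_cache)) sector_cache[[key]] else NULL
  if (is.null(sectors) ||
      !isTRUE(all.equal(sectors$geom_sig, c(record$contours$endo, record$contours$epi)))) {
    sectors <- build_sectors(record$contours$endo, record$contours$epi,
                             n_sectors = record$n_sectors,
                             reference_angle = reference_angle,
                             grid_dim = dim(myo))
    sectors$geom_sig <- c(record$contours$endo, record$contours$epi)
    if (!is.null(sector_cache)) sector_cache[[key]] <- sectors
  }

  tbl <- sector_table(list(ecv = ecv, native_t1 = t1n, fdg = suv), sectors,
                      patient = record$id, min_valid_frac = min_valid_frac)
  list(maps = list(native_t1 = t1n, post_t1 = t1p, ecv = ecv, fdg = suv),
       blood = blood, blood_suv = blood_suv, sectors = sectors,
       sector_table = tbl)
}

.pair_frame <- function(wide, mx, my) {
  data.frame(patient = wide$patient, x = wide[[mx]], y = wide[[my]])
}

#' Run the full statistical analysis on a cohort
#'
#' Derives ECV and SUV maps for every patient (optionally refitting T1 from
#' the MOLLI series), extracts co-localized sector values, computes biopsy
#' maximum/remote summaries with TBR variants, and assembles the
#' correlation battery: within- and between-subject correlations for the
#' three modality pairs, per-subject slopes, correlations of per-patient
#' maxima across modalities, cross-modality argmax distances, and
#' image-summary vs marker / infarct-size correlations.
#'
#' @param cohort list of `patient_record`s ([make_cohort()] or loaded from
#'   files).
#' @param use_molli_fit refit T1 maps pixelwise from the MOLLI series
#'   instead of using the stored T1 maps.
#' @param min_valid_frac sector exclusion threshold, see
#'   [extract_sector_values()].
#' @param markers optional marker table (`patient` + numeric columns);
#'   defaults to the cohort's own markers and ground-truth infarct size.
#' @param sector_cache optional environment for caching sector maps across
#'   calls (useful for replicate cohorts that share one slice geometry); a
#'   fresh cache is used when `NULL`.
#' @return An object of class `cohort_result`: `sectors`, `biopsy`,
#'   `image_summary`, `markers`, `pair_correlations`, `max_correlations`,
#'   `slopes`, `marker_correlations`, `distances`, `excluded_sectors`.
#' @export
analyze_cohort <- function(cohort, use_molli_fit = FALSE,
                           min_valid_frac = 0.5, markers = NULL,
                           sector_cache = NULL) {
  if (!length(cohort)) user_stopf("empty cohort")
  cache <- sector_cache %||% new.env(parent = emptyenv())
  per <- lapply(cohort, function(rec)
    process_patient(rec, use_molli_fit = use_molli_fit,
                    min_valid_frac = min_valid_frac, sector_cache = cache))
  sectors <- do.call(rbind, lapply(per, `[[`, "sector_table"))
  blood_suv <- data.frame(
    patient = vapply(cohort, `[[`, "", "id"),
    blood_suv = vapply(per, `[[`, numeric(1), "blood_suv"))
  analyze_from_sectors(sectors, blood_suv,
                       markers = markers %||% cohort_markers(cohort))
}

#' Assemble the correlation battery from a tidy sector table
#'
#' The statistics layer alone: takes an already-extracted sector table (plus
#' per-patient blood SUV for the TBR variants and a marker table) and
#' computes biopsy summaries and all correlations.  [analyze_cohort()] and
#' [run_pipeline()] both delegate here.
#'
#' @param sectors tidy sector table ([sector_table()] rows for all
#'   patients).
#' @param blood_suv data frame `patient`, `blood_suv` (LV blood-pool
#'   SUV-LBM).
#' @param markers data frame `patient` plus marker / infarct-size columns.
#' @return A `cohort_result` list, see [analyze_cohort()].
#' @export
analyze_from_sectors <- function(sectors, blood_suv, markers) {
  biopsy <- biopsy_summary(sectors)
  dist <- argmax_distances(biopsy)

  # wide image summary incl. blood-normalized (TBR) FDG variants
  w <- stats::reshape(
    biopsy[, c("patient", "modality", "max_value", "remote_value")],
    direction = "wide", idvar = "patient", timevar = "modality")
  names(w) <- sub("^max_value\\.", "max_", names(w))
  names(w) <- sub("^remote_value\\.", "remote_", names(w))
  w <- merge(w, blood_suv, by = "patient")
  w$max_fdg_tbr <- w$max_fdg / w$blood_suv
  w$remote_fdg_tbr <- w$remote_fdg / w$blood_suv
  image_summary <- w

  # paired sector values (non-excluded only)
  ok <- sectors[!sectors$excluded, ]
  wide <- stats::reshape(ok[, c("patient", "sector", "modality", "value")],
                         direction = "wide", idvar = c("patient", "sector"),
                         timevar = "modality")
  names(wide) <- sub("^value\\.", "", names(wide))
  pairs <- list(c("ecv", "fdg"), c("native_t1", "fdg"), c("ecv", "native_t1"))
  pair_correlations <- do.call(rbind, lapply(pairs, function(pr) {
    pd <- .pair_frame(wide, pr[1], pr[2])
    rbind(cbind(pair = paste(pr, collapse = "/"), between_subject_corr(pd)),
          cbind(pair = paste(pr, collapse = "/"), within_subject_corr(pd)))
  }))
  slopes <- do.call(rbind, lapply(pairs, function(pr)
    cbind(pair = paste(pr, collapse = "/"),
          per_subject_slopes(.pair_frame(wide, pr[1], pr[2])))))
  max_correlations <- do.call(rbind, lapply(pairs, function(pr) {
    pd <- data.frame(patient = image_summary$patient,
                     x = image_summary[[paste0("max_", pr[1])]],
                     y = image_summary[[paste0("max_", pr[2])]])
    ct <- stats::cor.test(pd$x, pd$y)
    data.frame(pair = paste(pr, collapse = "/"), kind = "max",
               r = unname(ct$estimate), p = ct$p.value,
               df = nrow(pd) - 2, n = nrow(pd))
  }))

  mcols <- intersect(c("ck", "ck_mb", "troponin_t", "leukocytes", "monocytes",
                       "infarct_size_pct_lv"), names(markers))
  markers <- markers[, c("patient", mcols), drop = FALSE]
  marker_corr <- marker_correlations(image_summary[, c("patient",
                                       grep("^(max|remote)_", names(image_summary), value = TRUE))],
                                     markers[, c("patient", mcols), drop = FALSE])

  structure(list(sectors = sectors, biopsy = biopsy,
                 image_summary = image_summary,
                 markers = markers,
                 pair_correlations = pair_correlations,
                 max_correlations = max_correlations,
                 slopes = slopes,
                 marker_correlations = marker_corr %||%
                   data.frame(image = character(), marker = character(),
                              n = integer(), r = numeric(), p = numeric()),
                 distances = dist,
                 excluded_sectors = sum(sectors$excluded) / length(unique(sectors$modality))),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  k <- length(unique(x$sectors$patient))
  n_sec <- sum(!x$sectors$excluded & x$sectors$modality == x$sectors$modality[1])
  cat(sprintf("<cohort_result> %d patients, %d analyzed sectors per signal\n", k, n_sec))
  w <- x$pair_correlations[x$pair_correlations$kind == "within", ]
  b <- x$pair_correlations[x$pair_correlations$kind == "between", ]
  for (i in seq_len(nrow(w)))
    cat(sprintf("  %-20s within R = %.2f, between R = %.2f\n",
                w$pair[i], w$r[i], b$r[b$pair == w$pair[i]]))
  invisible(x)
}
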