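# File formats: NIfTI for images, JSON for contours / ROIs / dose info,
# tidy CSV for tables.  Readers validate schemas and name the offending
# file or column in their error messages.

#' Write / read a scalar map as NIfTI
#'
#' Maps are stored as 32-bit float NIfTI; the validity mask is implicit
#' (non-finite pixels are invalid).
#'
#' @param map a [scalar_map()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `write_scalar_map` returns `path` invisibly; `read_scalar_map`
#'   returns a [scalar_map()].
#' @export
write_scalar_map <- function(map, path) {
  RNifti::writeNifti(map$data, path, datatype = "float")
  invisible(path)
}

#' @rdname write_scalar_map
#' @param quantity,units labels for the map read back (NIfTI does not carry
#'   them).
#' @export
read_scalar_map <- function(path, quantity = "value", units = "") {
  if (!file.exists(path)) user_stopf("image file not found: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) user_stopf("cannot read NIfTI file %s: %s",
                                                 path, conditionMessage(e)))
  d <- dim(img)
  if (length(d) > 2) d <- d[d > 1]
  if (length(d) != 2)
    user_stopf("image %s is not a 2D map (dims %s)", path,
               paste(dim(img), collapse = "x"))
  scalar_map(matrix(as.numeric(img), d[1], d[2]), quantity = quantity,
             units = units)
}

#' Write / read a MOLLI series (3D NIfTI + inversion-time CSV)
#'
#' @param series a [molli_series()].
#' @param image_path 3D NIfTI path.
#' @param times_path CSV with one effective inversion time (ms) per image,
#'   column `ti_ms`.
#' @return `write_molli_series` returns `image_path` invisibly.
#' @export
write_molli_series <- function(series, image_path, times_path) {
  RNifti::writeNifti(series$data, image_path, datatype = "float")
  utils::write.csv(data.frame(ti_ms = series$ti), times_path, row.names = FALSE)
  invisible(image_path)
}

#' @rdname write_molli_series
#' @param heart_rate bpm recorded with the series.
#' @export
read_molli_series <- function(image_path, times_path, heart_rate = NA_real_) {
  if (!file.exists(image_path)) user_stopf("image file not found: %s", image_path)
  img <- tryCatch(RNifti::readNifti(image_path),
                  error = function(e) user_stopf("cannot read NIfTI file %s: %s",
                                                 image_path, conditionMessage(e)))
  if (length(dim(img)) != 3)
    user_stopf("MOLLI series %s must be a 3D image", image_path)
  ti <- utils::read.csv(times_path)
  if (!identical(names(ti), "ti_ms"))
    user_stopf("times CSV %s must have exactly one column `ti_ms`", times_path)
  molli_series(array(as.numeric(img), dim(img)), ti$ti_ms,
               heart_rate = heart_rate)
}

#' Write / read endo- and epicardial contours as JSON
#'
#' @param contours list with `endo` and `epi` point matrices.
#' @param path JSON path.
#' @export
write_contours <- function(contours, path) {
  jsonlite::write_json(list(endo = unname(contours$endo),
                            epi = unname(contours$epi)),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) user_stopf("contours file not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("endo", "epi")) {
    if (is.null(j[[nm]]) || !is.matrix(j[[nm]]) || ncol(j[[nm]]) != 2)
      user_stopf("contours JSON %s: `%s` must be an n x 2 point list", path, nm)
    if (nrow(j[[nm]]) < 8)
      user_stopf("contours JSON %s: `%s` has %d points, need >= 8", path, nm,
                 nrow(j[[nm]]))
  }
  list(endo = j$endo, epi = j$epi)
}

#' Write / read a blood-ROI specification (cavity disks) as JSON
#'
#' @param roi list with `disks`: each `list(center = c(x, y), radius = r)`.
#' @param path JSON path.
#' @export
write_blood_roi <- function(roi, path) {
  jsonlite::write_json(list(disks = lapply(roi$disks, function(d)
    list(center = d$center, radius = d$radius))), path,
    digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_blood_roi
#' @param grid_dim image dimensions used to rasterize the disks into a mask.
#' @export
read_blood_roi <- function(path, grid_dim) {
  if (!file.exists(path)) user_stopf("blood ROI file not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$disks) || !length(j$disks))
    user_stopf("blood ROI JSON %s must contain `disks`", path)
  disks <- lapply(j$disks, function(d)
    list(center = as.numeric(unlist(d$center)), radius = as.numeric(d$radius)))
  mask <- Reduce(`|`, lapply(disks, function(d)
    disk_mask(d$center, d$radius, grid_dim)))
  list(disks = disks, mask = mask)
}

# strict tidy-CSV reader: exact column set, extra/missing columns rejected
read_checked_csv <- function(path, columns) {
  if (!file.exists(path)) user_stopf("table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  extra <- setdiff(names(df), columns)
  missing <- setdiff(columns, names(df))
  if (length(extra))
    user_stopf("table %s has unexpected column(s): %s", path,
               paste(extra, collapse = ", "))
  if (length(missing))
    user_stopf("table %s is missing column(s): %s", path,
               paste(missing, collapse = ", "))
  df[, columns]
}

marker_csv_columns <- c("patient", "ck", "ck_mb", "troponin_t", "leukocytes",
                        "monocytes", "infarct_size_pct_lv")

#' Write / read the cohort marker table as CSV
#'
#' Columns: `patient`, `ck`, `ck_mb`, `troponin_t`, `leukocytes`,
#' `monocytes` (peak values; U/l resp. G/l) and `infarct_size_pct_lv`.
#' Extra or missing columns are rejected by name.
#'
#' @param markers data frame of marker peaks.
#' @param path CSV path.
#' @export
write_markers <- function(markers, path) {
  utils::write.csv(markers[, intersect(marker_csv_columns, names(markers))],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  read_checked_csv(path, marker_csv_columns)
}

#' Write / read a per-patient metadata JSON (dose, biometrics, hematocrit)
#'
#' @param record a `patient_record`.
#' @param path JSON path.
#' @export
write_patient_meta <- function(record, path) {
  jsonlite::write_json(list(
    id = record$id, n_sectors = record$n_sectors, hct = record$hct,
    heart_rate = record$heart_rate, sex = record$sex,
    weight = record$weight, height = record$height,
    injected_dose = record$dose$injected_dose,
    uptake_min = record$dose$uptake_min,
    half_life = record$dose$half_life), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_patient_meta
#' @export
read_patient_meta <- function(path) {
  if (!file.exists(path)) user_stopf("meta file not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("id", "n_sectors", "hct", "heart_rate", "sex", "weight", "height",
            "injected_dose", "uptake_min", "half_life")
  missing <- setdiff(need, names(j))
  if (length(missing))
    user_stopf("meta JSON %s is missing field(s): %s", path,
               paste(missing, collapse = ", "))
  j
}

#' Write a patient record to a directory
#'
#' Layout: `native_t1.nii.gz`, `post_t1.nii.gz`, `pet_activity.nii.gz`,
#' optional MOLLI series (`molli_native.nii.gz` + `molli_native_times.csv`,
#' same for post), `contours.json`, `blood_roi.json`, `meta.json`.
#'
#' @param record a `patient_record`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_patient_record <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("native_t1", "post_t1", "pet_activity"))
    write_scalar_map(record$maps[[nm]], file.path(dir, paste0(nm, ".nii.gz")))
  if (!is.null(record$molli)) {
    for (nm in names(record$molli))
      write_molli_series(record$molli[[nm]],
                         file.path(dir, sprintf("molli_%s.nii.gz", nm)),
                         file.path(dir, sprintf("molli_%s_times.csv", nm)))
  }
  write_contours(record$contours, file.path(dir, "contours.json"))
  write_blood_roi(record$blood_roi, file.path(dir, "blood_roi.json"))
  write_patient_meta(record, file.path(dir, "meta.json"))
  invisible(dir)
}

#' Read a patient record from a directory written by [write_patient_record()]
#'
#' The myocardial mask is rebuilt from the contours; the blood ROI from its
#' disk specification.  Ground-truth fields are not part of the file
#' interface (they exist only inside generated records).
#'
#' @param dir patient directory.
#' @param markers optional named numeric vector of this patient's marker
#'   peaks.
#' @return A `patient_record`.
#' @export
read_patient_record <- function(dir, markers = NULL) {
  meta <- read_patient_meta(file.path(dir, "meta.json"))
  contours <- read_contours(file.path(dir, "contours.json"))
  t1n <- read_scalar_map(file.path(dir, "native_t1.nii.gz"), "native_t1", "ms")
  t1p <- read_scalar_map(file.path(dir, "post_t1.nii.gz"), "post_t1", "ms")
  act <- read_scalar_map(file.path(dir, "pet_activity.nii.gz"),
                         "pet_activity", "kBq/ml")
  check_same_grid(t1n, t1p, sprintf("maps in %s", dir))
  check_same_grid(t1n, act, sprintf("maps in %s", dir))
  myo <- annulus_mask(contours$endo, contours$epi, dim(t1n$data))
  for (m in c("t1n", "t1p", "act")) {
    x <- get(m)
    x$mask <- x$mask & myo
    assign(m, x)
  }
  roi <- read_blood_roi(file.path(dir, "blood_roi.json"), dim(t1n$data))
  molli <- NULL
  if (file.exists(file.path(dir, "molli_native.nii.gz"))) {
    molli <- list(
      native = read_molli_series(file.path(dir, "molli_native.nii.gz"),
                                 file.path(dir, "molli_native_times.csv"),
                                 meta$heart_rate),
      post = read_molli_series(file.path(dir, "molli_post.nii.gz"),
                               file.path(dir, "molli_post_times.csv"),
                               meta$heart_rate))
  }
  structure(list(
    id = meta$id, n_sectors = as.integer(meta$n_sectors), hct = meta$hct,
    heart_rate = meta$heart_rate, sex = meta$sex, weight = meta$weight,
    height = meta$height,
    dose = pet_dose_info(meta$injected_dose, meta$uptake_min, meta$weight,
                         meta$height, meta$sex, meta$half_life),
    contours = contours, blood_roi = roi,
    maps = list(native_t1 = t1n, post_t1 = t1p, pet_activity = act),
    molli = molli, markers = markers, truth = NULL, params = NULL),
    class = "patient_record")
}
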