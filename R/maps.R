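#' 2D scalar map with a validity mask
#'
#' The basic image container of the package: one 2D grid of a single
#' quantity (native T1 in ms, ECV as a fraction, PET activity in kBq/ml,
#' SUV, ...) plus a logical validity mask of the same dimensions.  Pixels
#' outside the mask may still carry data (e.g. blood-pool values inside the
#' LV cavity) but are never part of myocardial statistics.
#'
#' @param data numeric matrix of pixel values.
#' @param mask logical matrix of the same dimensions; defaults to
#'   `is.finite(data)`.
#' @param quantity short label of what the map holds, e.g. `"native_t1"`,
#'   `"ecv"`, `"suv"`, `"pet_activity"`.
#' @param units unit string, e.g. `"ms"`, `"fraction"`, `"kBq/ml"`.
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(data, mask = NULL, quantity = "value", units = "") {
  if (!is.matrix(data) || !is.numeric(data))
    user_stopf("`data` must be a numeric matrix")
  if (is.null(mask)) mask <- is.finite(data)
  if (!is.logical(mask) || !identical(dim(mask), dim(data)))
    user_stopf("`mask` must be a logical matrix with the same dimensions as `data`")
  mask <- mask & is.finite(data)
  structure(list(data = data, mask = mask, quantity = quantity, units = units),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$data[x$mask]
  cat(sprintf("<scalar_map> %s [%s], %d x %d, %d valid pixels",
              x$quantity, x$units, nrow(x$data), ncol(x$data), sum(x$mask)))
  if (length(v))
    cat(sprintf(", range %.4g..%.4g", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' @export
dim.scalar_map <- function(x) dim(x$data)

check_same_grid <- function(a, b, what = "maps") {
  if (!identical(dim(a), dim(b)))
    user_stopf("%s do not share one grid (%s vs %s)", what,
               paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

#' Stack of MOLLI magnitude images with per-image inversion times
#'
#' @param data numeric array `nx x ny x n_images` of magnitude signals, in
#'   acquisition order.
#' @param ti numeric vector of effective inversion times (ms), one per image,
#'   in the same order as the third array dimension.
#' @param heart_rate heart rate (bpm) the schedule was computed for.
#' @param scheme the [molli_scheme()] used.
#' @return An object of class `molli_series`.
#' @export
molli_series <- function(data, ti, heart_rate = NA_real_, scheme = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    user_stopf("`data` must be a 3D array (nx x ny x n_images)")
  if (length(ti) != dim(data)[3L])
    user_stopf("length(ti) = %d does not match %d images", length(ti), dim(data)[3L])
  if (any(!is.finite(ti)) || any(ti <= 0))
    user_stopf("inversion times must be finite and strictly positive")
  structure(list(data = data, ti = as.numeric(ti), heart_rate = heart_rate,
                 scheme = scheme),
            class = "molli_series")
}

#' @export
print.molli_series <- function(x, ...) {
  cat(sprintf("<molli_series> %d x %d x %d images, TI %.0f..%.0f ms\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$ti), max(x$ti)))
  invisible(x)
}
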