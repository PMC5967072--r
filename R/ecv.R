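# ECV mapping from registered native / post-contrast T1 and hematocrit.

#' Blood-pool T1 sample
#'
#' Native and post-contrast blood T1 taken as the median over a cavity
#' (LV-centric) region of interest.  The median is used for robustness to
#' partial-volume pixels at the cavity border.
#'
#' @param native_map,post_map [scalar_map()]s of native and post-contrast T1
#'   (ms), sharing one grid.
#' @param roi logical matrix selecting the blood ROI pixels.
#' @return An object of class `blood_pool_sample` with fields
#'   `native_t1_blood`, `post_t1_blood` (ms) and `n_pixels`.
#' @export
blood_pool_sample <- function(native_map, post_map, roi) {
  check_same_grid(native_map, post_map, "T1 maps")
  if (!is.logical(roi) || !identical(dim(roi), dim(native_map$data)))
    user_stopf("`roi` must be a logical matrix on the map grid")
  nv <- native_map$data[roi]
  pv <- post_map$data[roi]
  keep <- is.finite(nv) & is.finite(pv)
  if (!any(keep)) user_stopf("blood ROI contains no finite T1 pairs")
  b <- structure(list(native_t1_blood = stats::median(nv[keep]),
                      post_t1_blood = stats::median(pv[keep]),
                      n_pixels = sum(keep)),
                 class = "blood_pool_sample")
  validate_blood_pool(b)
  b
}

validate_blood_pool <- function(b) {
  if (!is.finite(b$native_t1_blood) || !is.finite(b$post_t1_blood) ||
      b$native_t1_blood <= 0 || b$post_t1_blood <= 0)
    user_stopf("blood T1 values must be positive")
  if (b$post_t1_blood >= b$native_t1_blood)
    user_stopf("post-contrast blood T1 (%.1f ms) must be shorter than native (%.1f ms): contrast equilibration violated",
               b$post_t1_blood, b$native_t1_blood)
  invisible(b)
}

#' @export
print.blood_pool_sample <- function(x, ...) {
  cat(sprintf("<blood_pool_sample> native %.1f ms, post %.1f ms (%d px)\n",
              x$native_t1_blood, x$post_t1_blood, x$n_pixels))
  invisible(x)
}

# accept hematocrit given as a percentage (both conventions are common in
# source CSVs); fractions above 1 are auto-detected and divided by 100
normalize_hct <- function(hct) {
  chk_num(hct, "hct", lo = 0, hi = 100)
  if (hct >= 1) {
    warnf("hematocrit %g > 1 interpreted as percent and divided by 100", hct)
    hct <- hct / 100
  }
  hct
}

#' Pixelwise extracellular volume fraction
#'
#' The standard two-point equilibrium formulation:
#' `ECV = (1 - Hct) * dR1_myo / dR1_blood` with `R1 = 1/T1` and
#' `dR1 = 1/T1_post - 1/T1_native`.  A negative myocardial dR1 (apparent
#' contrast washout) yields `NA` for that pixel — flagged, not an error —
#' while a non-positive blood dR1 violates the equilibration assumption and
#' is an error.
#'
#' @param native_t1_myo,post_t1_myo myocardial T1 (ms); vectors or matrices.
#' @param blood a [blood_pool_sample()] (or list with `native_t1_blood`,
#'   `post_t1_blood`).
#' @param hct hematocrit as a fraction in (0, 1); values above 1 are taken
#'   as percent and divided by 100 with a warning.
#' @return ECV as a fraction, same shape as the myocardial inputs; `NA`
#'   where the pixel is invalid.
#' @export
compute_ecv <- function(native_t1_myo, post_t1_myo, blood, hct) {
  hct <- normalize_hct(hct)
  validate_blood_pool(blood)
  dr1_blood <- 1 / blood$post_t1_blood - 1 / blood$native_t1_blood
  bad_t1 <- !is.finite(native_t1_myo) | !is.finite(post_t1_myo) |
    native_t1_myo <= 0 | post_t1_myo <= 0
  dr1_myo <- 1 / post_t1_myo - 1 / native_t1_myo
  ecv <- (1 - hct) * dr1_myo / dr1_blood
  ecv[bad_t1 | dr1_myo < 0] <- NA_real_
  ecv
}

#' Pixelwise ECV map from registered T1 maps
#'
#' Applies [compute_ecv()] on the intersection of the two validity masks.
#' Pixels with invalid ECV (non-positive T1 or negative myocardial dR1) are
#' dropped from the returned mask; the count is reported in a message and in
#' the `"n_excluded"` attribute.
#'
#' @param native,post [scalar_map()]s of native and post-contrast T1 (ms).
#' @param blood a [blood_pool_sample()].
#' @param hct hematocrit fraction (see [compute_ecv()]).
#' @return A [scalar_map()] of ECV (fraction) with attribute `n_excluded`.
#' @export
compute_ecv_map <- function(native, post, blood, hct) {
  check_same_grid(native, post, "T1 maps")
  mask <- native$mask & post$mask
  ecv <- matrix(NA_real_, nrow(native$data), ncol(native$data))
  ecv[mask] <- compute_ecv(native$data[mask], post$data[mask], blood, hct)
  out_mask <- mask & is.finite(ecv)
  n_excluded <- sum(mask) - sum(out_mask)
  if (n_excluded > 0)
    message(sprintf("compute_ecv_map: %d of %d pixels invalid (dropped from mask)",
                    n_excluded, sum(mask)))
  m <- scalar_map(ecv, out_mask, quantity = "ecv", units = "fraction")
  attr(m, "n_excluded") <- n_excluded
  m
}
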