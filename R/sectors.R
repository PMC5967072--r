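# Centerline sector segmentation of the myocardial annulus.
#
# Endo- and epicardial contours are matched by equal-angle resampling about
# the cavity centroid; the centerline is the pointwise midpoint curve.  Its
# arc length is divided into n equal half-open segments starting at the
# reference angle, and every annulus pixel is assigned to the segment of its
# nearest centerline arc position (transmural assignment).  Sector ids
# increase counter-clockwise from the reference angle.

# periodic radius function of a star-shaped contour, sampled at `angles`
.contour_radius_at <- function(pts, centroid, angles, what = "contour") {
  if (!is.matrix(pts) || ncol(pts) != 2 || nrow(pts) < 8)
    user_stopf("%s must be a matrix of >= 8 (x, y) points", what)
  dx <- pts[, 1] - centroid[1]
  dy <- pts[, 2] - centroid[2]
  a <- atan2(dy, dx)
  r <- sqrt(dx^2 + dy^2)
  # a simple star-shaped contour sweeps the angle monotonically (one
  # consistent direction); folds indicate self-intersection or a shape the
  # equal-angle matching cannot represent
  step <- wrap_angle(diff(a))
  if (any(step > 0) && any(step < 0))
    user_stopf("%s is self-intersecting or not star-shaped about the cavity centroid", what)
  ord <- order(a)
  a <- a[ord]; r <- r[ord]
  if (anyDuplicated(a))
    user_stopf("%s is not star-shaped about the cavity centroid (duplicate angles)", what)
  # periodic extension for interpolation across the -pi/pi seam
  ae <- c(a[length(a)] - 2 * pi, a, a[1] + 2 * pi)
  re <- c(r[length(r)], r, r[1])
  stats::approx(ae, re, xout = wrap_angle(angles), rule = 2)$y
}

#' Build a centerline sector map for an annulus
#'
#' @param endo,epi ordered (x, y) point matrices of the endo- and
#'   epicardial contours; `epi` must enclose `endo` and both must be
#'   star-shaped about the cavity centroid (self-intersecting contours are
#'   rejected).
#' @param n_sectors 32 (basal/mid) or 16 (apical).
#' @param reference_angle start angle of sector 1 (radians; 0 = image +x
#'   axis, counter-clockwise).
#' @param grid_dim image dimensions `c(nx, ny)` for the label image.
#' @param centerline_samples number of equal-angle centerline samples; the
#'   default (704) is a multiple of both 16 and 32 so that rotating the
#'   reference angle by a whole sector permutes labels exactly on
#'   rotationally symmetric geometry.
#' @return An object of class `sector_map`: `labels` (integer matrix, 0 =
#'   outside), `n_sectors`, `centerline` (sample points), `arc_pos`,
#'   `reference_angle`.
#' @export
build_sectors <- function(endo, epi, n_sectors = 32, reference_angle = 0,
                          grid_dim, centerline_samples = 704L) {
  if (!n_sectors %in% c(16L, 32L))
    user_stopf("n_sectors must be 16 or 32, got %s", n_sectors)
  n_sectors <- as.integer(n_sectors)
  m <- as.integer(centerline_samples)
  centroid <- colMeans(endo)

  angles <- reference_angle + 2 * pi * (seq_len(m) - 1L) / m
  r_endo <- .contour_radius_at(endo, centroid, angles, "endo contour")
  r_epi <- .contour_radius_at(epi, centroid, angles, "epi contour")
  if (any(r_epi <= r_endo))
    user_stopf("epi contour does not enclose endo contour at all angles")

  mid <- cbind(centroid[1] + (r_endo + r_epi) / 2 * cos(angles),
               centroid[2] + (r_endo + r_epi) / 2 * sin(angles))
  seg <- sqrt(rowSums((mid - mid[c(2:m, 1), ])^2))  # seg[j]: mid_j -> mid_j+1
  arc <- c(0, cumsum(seg[-m]))                      # arc position of sample j
  total <- sum(seg)
  # half-open [start, end) bins in arc length; samples numerically on a bin
  # boundary are snapped to it so the partition is stable under rotations
  # of the reference angle
  u <- arc / (total / n_sectors)
  near <- abs(u - round(u)) < 1e-9
  u[near] <- round(u[near])
  sector_of_sample <- pmin(n_sectors, as.integer(floor(u)) + 1L)

  myo <- annulus_mask(endo, epi, grid_dim)
  idx <- which(myo)
  px <- cbind((idx - 1L) %% grid_dim[1] + 1L, (idx - 1L) %/% grid_dim[1] + 1L)

  labels <- matrix(0L, grid_dim[1], grid_dim[2])
  chunk <- 2048L
  for (start in seq(1L, length(idx), by = chunk)) {
    rows <- start:min(start + chunk - 1L, length(idx))
    d2 <- outer(px[rows, 1], mid[, 1], "-")^2 + outer(px[rows, 2], mid[, 2], "-")^2
    nearest <- max.col(-d2, ties.method = "first")
    labels[idx[rows]] <- sector_of_sample[nearest]
  }

  structure(list(labels = labels, n_sectors = n_sectors, centerline = mid,
                 arc_pos = arc, sector_of_sample = sector_of_sample,
                 reference_angle = reference_angle, centroid = centroid),
            class = "sector_map")
}

#' @export
print.sector_map <- function(x, ...) {
  cat(sprintf("<sector_map> %d sectors, %d annulus pixels, reference angle %.3f rad\n",
              x$n_sectors, sum(x$labels > 0), x$reference_angle))
  invisible(x)
}

#' Per-sector mean values of a map
#'
#' Mean of valid pixels per sector.  A sector whose valid-pixel fraction
#' falls below `min_valid_frac` (or that is empty after masking) is flagged
#' excluded with a reason — flagged, not raised, mirroring how artifact
#' segments are dropped from analysis rather than aborting it.
#'
#' @param map a [scalar_map()] on the same grid as `sectors`.
#' @param sectors a [sector_map()].
#' @param min_valid_frac minimum fraction of a sector's pixels that must be
#'   valid (default 0.5).
#' @return Data frame with one row per sector: `sector`, `value`,
#'   `n_pixels`, `n_valid`, `excluded`, `reason`.
#' @export
extract_sector_values <- function(map, sectors, min_valid_frac = 0.5) {
  if (!inherits(sectors, "sector_map")) user_stopf("`sectors` must be a sector_map")
  if (!identical(dim(map$data), dim(sectors$labels)))
    user_stopf("map and sector map do not share one grid")
  n <- sectors$n_sectors
  lab <- sectors$labels
  inside <- lab > 0L
  n_pixels <- tabulate(lab[inside], nbins = n)
  valid <- inside & map$mask & is.finite(map$data)
  n_valid <- tabulate(lab[valid], nbins = n)
  sums <- rep(0, n)
  if (any(valid)) {
    s <- rowsum(map$data[valid], lab[valid])
    sums[as.integer(rownames(s))] <- s[, 1]
  }
  value <- ifelse(n_valid > 0, sums / n_valid, NA_real_)
  frac <- ifelse(n_pixels > 0, n_valid / n_pixels, 0)
  excluded <- n_valid == 0L | frac < min_valid_frac
  reason <- rep(NA_character_, n)
  reason[excluded] <- ifelse(n_valid[excluded] == 0L, "empty after masking",
                             "valid-pixel fraction below threshold")
  data.frame(sector = seq_len(n), value = value, n_pixels = n_pixels,
             n_valid = n_valid, excluded = excluded, reason = reason)
}

#' Tidy per-sector table for the three registered image signals
#'
#' Extracts per-sector means for each modality on a shared sector frame and
#' propagates exclusions across modalities: a sector excluded in one signal
#' (artifact, empty) is excluded in all three, keeping the co-localized
#' frame intact.  ECV maps (stored as fractions) are rendered in percent.
#'
#' @param maps named list of [scalar_map()]s, e.g.
#'   `list(ecv =, native_t1 =, fdg =)`.
#' @param sectors a [sector_map()].
#' @param patient patient id for the `patient` column.
#' @param min_valid_frac see [extract_sector_values()].
#' @return Tidy data frame: `patient`, `sector`, `modality`, `value`,
#'   `excluded`, `reason`, `n_sectors`.
#' @export
sector_table <- function(maps, sectors, patient = "P01", min_valid_frac = 0.5) {
  stopifnot(is.list(maps), length(names(maps)) == length(maps))
  per <- lapply(names(maps), function(nm) {
    df <- extract_sector_values(maps[[nm]], sectors, min_valid_frac)
    if (identical(maps[[nm]]$quantity, "ecv") &&
        identical(maps[[nm]]$units, "fraction"))
      df$value <- df$value * 100
    df$modality <- nm
    df
  })
  excluded_any <- Reduce(`|`, lapply(per, function(d) d$excluded))
  out <- do.call(rbind, lapply(per, function(d) {
    co <- excluded_any & !d$excluded
    d$reason[co] <- "excluded in co-localized modality"
    d$excluded <- excluded_any
    data.frame(patient = patient, sector = d$sector, modality = d$modality,
               value = d$value, excluded = d$excluded, reason = d$reason,
               n_sectors = sectors$n_sectors)
  }))
  rownames(out) <- NULL
  out
}
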