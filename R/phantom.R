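# Synthetic single-slice phantom: an LV annulus with a contiguous infarct
# wedge whose severity peaks at its core, co-localized elevations in native
# T1 / ECV / FDG, blood-pool disks inside the cavity, and (optionally) the
# MOLLI magnitude series the T1 maps would have been fitted from.

#' Parameters of a synthetic short-axis phantom patient
#'
#' Defaults are anchored to the scale of values reported for reperfused
#' acute infarction at 3T: remote ECV 27.8%, maximum ECV 57%, remote native
#' T1 1163 ms, maximum 1432 ms, remote FDG 0.71 SUV-LBM, maximum 2.62,
#' infarct size 17.3 %LV (wedge half-width 0.173*pi), heart rate 62 bpm.
#' The per-patient `*_gain` values are the severity-scaled elevations at the
#' wedge core, i.e. the designed pixel value at the infarct center is
#' `remote + gain`.
#'
#' @param grid_size pixels per side (odd sizes put the cavity center on a
#'   pixel).
#' @param endo_radius,epi_radius endo/epicardial radii (pixels);
#'   `0 < endo < epi < grid_size/2`.
#' @param n_sectors 32 (basal/mid slices) or 16 (apical).
#' @param infarct_center_angle,infarct_half_width wedge center and angular
#'   half-width (radians); the ground-truth infarct size is
#'   `half_width / pi * 100` %LV.
#' @param remote_t1,remote_ecv,remote_fdg remote (non-infarcted) levels:
#'   ms, fraction in (0,1), SUV-LBM.
#' @param t1_gain,ecv_gain,fdg_gain per-patient maxima of the
#'   severity-scaled elevations (ms, fraction, SUV-LBM).
#' @param hematocrit fraction in (0, 1).
#' @param heart_rate bpm (sets the MOLLI TI schedule).
#' @param noise_sd Gaussian noise SD on MOLLI magnitude signals, in signal
#'   units of the `molli_a = 100` scale (`noise_sd = 2` is SNR 50).
#' @param map_noise `NULL` or `list(t1 =, post_t1 =, suv =)`: noise SDs on
#'   the stored maps (ms, ms, SUV).  `NULL` scales the defaults
#'   (15 ms / 8 ms / 0.05 SUV at `noise_sd = 2`) proportionally with
#'   `noise_sd`, so `noise_sd = 0` gives a fully noise-free phantom.
#' @param native_t1_blood,post_t1_blood,blood_suv blood-pool levels carried
#'   by two cavity disks (ms, ms, SUV).
#' @param injected_dose,uptake_min,half_life,weight,height,sex PET dose and
#'   biometrics ([pet_dose_info()]).
#' @param scheme MOLLI acquisition scheme ([molli_scheme()]).
#' @param molli_a,molli_b MOLLI signal model amplitudes.
#' @param seed integer seed; all phantom randomness flows from it.
#' @return A validated parameter list of class `phantom_params`.
#' @export
phantom_params <- function(grid_size = 95,
                           endo_radius = 16, epi_radius = 26,
                           n_sectors = 32,
                           infarct_center_angle = 0,
                           infarct_half_width = 0.173 * pi,
                           remote_t1 = 1163, remote_ecv = 0.278,
                           remote_fdg = 0.71,
                           t1_gain = 269, ecv_gain = 0.292, fdg_gain = 1.91,
                           hematocrit = 0.42, heart_rate = 62,
                           noise_sd = 2, map_noise = NULL,
                           native_t1_blood = 1900, post_t1_blood = 350,
                           blood_suv = 0.7,
                           injected_dose = 311, uptake_min = 144,
                           half_life = 109.77,
                           weight = 85, height = 175, sex = "male",
                           scheme = molli_scheme(),
                           molli_a = 100, molli_b = 200,
                           seed = 1L) {
  p <- list(grid_size = as.integer(grid_size), endo_radius = endo_radius,
            epi_radius = epi_radius, n_sectors = as.integer(n_sectors),
            infarct_center_angle = infarct_center_angle,
            infarct_half_width = infarct_half_width,
            remote_t1 = remote_t1, remote_ecv = remote_ecv,
            remote_fdg = remote_fdg,
            t1_gain = t1_gain, ecv_gain = ecv_gain, fdg_gain = fdg_gain,
            hematocrit = hematocrit, heart_rate = heart_rate,
            noise_sd = noise_sd, map_noise = map_noise,
            native_t1_blood = native_t1_blood,
            post_t1_blood = post_t1_blood, blood_suv = blood_suv,
            injected_dose = injected_dose, uptake_min = uptake_min,
            half_life = half_life,
            weight = weight, height = height, sex = sex,
            scheme = scheme, molli_a = molli_a, molli_b = molli_b,
            seed = as.integer(seed))
  class(p) <- "phantom_params"
  validate_phantom_params(p)
}

validate_phantom_params <- function(p) {
  chk_num(p$grid_size, "grid_size", lo = 16, hi = 4096)
  chk_num(p$endo_radius, "endo_radius", lo = 0, open = TRUE, hi = Inf)
  if (!(p$endo_radius < p$epi_radius && p$epi_radius < p$grid_size / 2))
    user_stopf("need 0 < endo_radius < epi_radius < grid_size/2 (got %g, %g, %d): annulus empty or truncated",
               p$endo_radius, p$epi_radius, p$grid_size)
  if (!p$n_sectors %in% c(16L, 32L))
    user_stopf("n_sectors must be 16 or 32, got %d", p$n_sectors)
  chk_num(p$infarct_half_width, "infarct_half_width", lo = 0, hi = pi)
  chk_num(p$hematocrit, "hematocrit", lo = 0, hi = 1, open = TRUE)
  chk_num(p$remote_ecv, "remote_ecv", lo = 0, hi = 1, open = TRUE)
  chk_num(p$remote_t1, "remote_t1", lo = 0, open = TRUE, hi = Inf)
  chk_num(p$remote_fdg, "remote_fdg", lo = 0, open = TRUE, hi = Inf)
  chk_num(p$heart_rate, "heart_rate", lo = 20, hi = 250)
  chk_num(p$noise_sd, "noise_sd", lo = 0)
  if (p$ecv_gain < 0 || p$remote_ecv + p$ecv_gain >= 1)
    user_stopf("ecv_gain must keep peak ECV inside (0, 1)")
  if (p$t1_gain < 0 || p$fdg_gain < 0)
    user_stopf("gains must be non-negative")
  if (p$post_t1_blood >= p$native_t1_blood)
    user_stopf("post-contrast blood T1 must be shorter than native blood T1")
  p
}

# map-noise SDs: defaults scale proportionally with the MOLLI noise level
resolve_map_noise <- function(p) {
  if (!is.null(p$map_noise)) {
    mn <- p$map_noise
    if (!all(c("t1", "post_t1", "suv") %in% names(mn)))
      user_stopf("map_noise must name t1, post_t1 and suv")
    return(mn)
  }
  s <- p$noise_sd / 2
  list(t1 = 15 * s, post_t1 = 8 * s, suv = 0.05 * s)
}

# --- geometry helpers shared with the segmentation module -----------------

# closed circle contour, counter-clockwise from angle 0
circle_contour <- function(center, radius, n = 64L) {
  a <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(x = center[1] + radius * cos(a), y = center[2] + radius * sin(a))
}

# logical mask of pixel centers inside a polygon (rows = x, cols = y)
polygon_mask <- function(poly, dim) {
  poly <- rbind(poly, poly[1L, , drop = FALSE])
  pts <- cbind(rep(seq_len(dim[1]), times = dim[2]),
               rep(seq_len(dim[2]), each = dim[1]))
  matrix(mgcv::in.out(poly, pts), dim[1], dim[2])
}

annulus_mask <- function(endo, epi, dim) {
  m <- polygon_mask(epi, dim) & !polygon_mask(endo, dim)
  if (!any(m)) user_stopf("geometry yields an empty annulus")
  m
}

disk_mask <- function(center, radius, dim) {
  x <- matrix(seq_len(dim[1]), dim[1], dim[2])
  y <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  (x - center[1])^2 + (y - center[2])^2 <= radius^2
}

# raised-cosine wedge severity profile, peak 1 at the center angle,
# zero outside |dtheta| > half_width; constant transmurally
severity_profile <- function(theta, center, half_width) {
  d <- abs(wrap_angle(theta - center))
  s <- numeric(length(theta))
  if (half_width > 0) {
    inside <- d < half_width
    s[inside] <- 0.5 * (1 + cos(pi * d[inside] / half_width))
  }
  dim(s) <- dim(theta)
  s
}

# memoized slice geometry: phantom cohorts share one grid and radii, so the
# polygon masks and the pixel angle field are computed once per geometry
.geom_cache <- new.env(parent = emptyenv())

.phantom_geometry <- function(n, endo_radius, epi_radius) {
  key <- sprintf("%d_%.8g_%.8g", n, endo_radius, epi_radius)
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  endo <- circle_contour(ctr, endo_radius)
  epi <- circle_contour(ctr, epi_radius)
  myo <- annulus_mask(endo, epi, c(n, n))
  x <- matrix(seq_len(n), n, n)
  y <- matrix(seq_len(n), n, n, byrow = TRUE)
  theta <- atan2(y - ctr[2], x - ctr[1])
  disk_r <- endo_radius * 0.35
  off <- endo_radius * 0.45
  disks <- list(list(center = c(ctr[1] - off, ctr[2]), radius = disk_r),
                list(center = c(ctr[1] + off, ctr[2]), radius = disk_r))
  blood <- disk_mask(disks[[1]]$center, disk_r, c(n, n)) |
    disk_mask(disks[[2]]$center, disk_r, c(n, n))
  g <- list(ctr = ctr, endo = endo, epi = epi, myo = myo, theta = theta,
            disks = disks, blood = blood)
  .geom_cache[[key]] <- g
  g
}

# --- phantom ---------------------------------------------------------------

#' Generate one synthetic phantom patient
#'
#' Builds the myocardial annulus between circular endo/epicardial contours,
#' lays a raised-cosine severity wedge `s(theta)` into it, and derives all
#' maps so that the ground-truth pixel values are `remote + gain * s(theta)`
#' for native T1, ECV and FDG SUV.  The post-contrast T1 map is computed by
#' inverting the ECV equation, so the true pixel ECV given the blood-pool T1
#' pair and hematocrit reproduces the designed field exactly.  Two blood
#' disks inside the cavity carry the blood-pool T1 pair and blood activity.
#' With `include_molli = TRUE` the MOLLI magnitude series (native and
#' post-contrast) are generated from the true T1 maps with the phantom's
#' signal model and TI schedule.
#'
#' All randomness (map noise, MOLLI noise) flows from `params$seed`; the
#' caller's RNG state is untouched.
#'
#' @param params a [phantom_params()].
#' @param include_molli generate the MOLLI series (slower, larger).
#' @return An object of class `patient_record`: contours, maps, blood ROI,
#'   hematocrit, dose info, markers slot (filled by [make_cohort()]), and a
#'   `truth` list with the severity field, designed value fields, gains,
#'   blood levels and ground-truth infarct size (%LV).
#' @export
make_phantom <- function(params = phantom_params(), include_molli = FALSE) {
  p <- validate_phantom_params(params)
  with_seed(p$seed, {
    n <- p$grid_size
    geom <- .phantom_geometry(n, p$endo_radius, p$epi_radius)
    ctr <- geom$ctr
    endo <- geom$endo
    epi <- geom$epi
    myo <- geom$myo
    sev <- severity_profile(geom$theta, p$infarct_center_angle,
                            p$infarct_half_width)
    sev[!myo] <- 0

    # blood-pool: two disks inside the endo contour
    disks <- geom$disks
    blood <- geom$blood

    # ground-truth fields
    t1n_true <- matrix(NA_real_, n, n)
    t1p_true <- matrix(NA_real_, n, n)
    ecv_true <- matrix(NA_real_, n, n)
    suv_true <- matrix(NA_real_, n, n)
    t1n_true[myo] <- p$remote_t1 + p$t1_gain * sev[myo]
    ecv_true[myo] <- p$remote_ecv + p$ecv_gain * sev[myo]
    suv_true[myo] <- p$remote_fdg + p$fdg_gain * sev[myo]
    dr1_blood <- 1 / p$post_t1_blood - 1 / p$native_t1_blood
    t1p_true[myo] <- 1 / (1 / t1n_true[myo] +
                            ecv_true[myo] * dr1_blood / (1 - p$hematocrit))
    t1n_true[blood] <- p$native_t1_blood
    t1p_true[blood] <- p$post_t1_blood
    suv_true[blood] <- p$blood_suv

    dose <- pet_dose_info(p$injected_dose, p$uptake_min, p$weight, p$height,
                          p$sex, p$half_life)
    act_per_suv <- .suv_denominator(dose)          # kBq/ml per SUV unit
    act_true <- suv_true * act_per_suv

    mn <- resolve_map_noise(p)
    valid <- myo | blood
    noisy <- function(truth, sd) {
      out <- truth
      if (sd > 0) out[valid] <- out[valid] + stats::rnorm(sum(valid), 0, sd)
      out
    }
    maps <- list(
      native_t1 = scalar_map(noisy(t1n_true, mn$t1), myo, "native_t1", "ms"),
      post_t1 = scalar_map(noisy(t1p_true, mn$post_t1), myo, "post_t1", "ms"),
      pet_activity = scalar_map(noisy(act_true, mn$suv * act_per_suv), myo,
                                "pet_activity", "kBq/ml"))

    molli <- NULL
    if (include_molli) {
      ti <- molli_ti(p$scheme, p$heart_rate)
      build_series <- function(t1_field) {
        arr <- array(0, dim = c(n, n, length(ti)))
        t1v <- t1_field[valid]
        for (t in seq_along(ti)) {
          sl <- matrix(0, n, n)
          s <- molli_signal(ti[t], t1v, a = p$molli_a, b = p$molli_b)
          if (p$noise_sd > 0) s <- s + stats::rnorm(length(s), 0, p$noise_sd)
          sl[valid] <- s
          arr[, , t] <- sl
        }
        molli_series(arr, ti, heart_rate = p$heart_rate, scheme = p$scheme)
      }
      molli <- list(native = build_series(t1n_true),
                    post = build_series(t1p_true))
    }

    structure(list(
      id = sprintf("P%02d", 1L), n_sectors = p$n_sectors,
      hct = p$hematocrit, heart_rate = p$heart_rate,
      sex = p$sex, weight = p$weight, height = p$height,
      dose = dose,
      contours = list(endo = endo, epi = epi),
      blood_roi = list(disks = disks, mask = blood),
      maps = maps, molli = molli,
      markers = NULL,
      truth = list(severity = sev, native_t1 = t1n_true, post_t1 = t1p_true,
                   ecv = ecv_true, suv = suv_true,
                   infarct_size_pct_lv = p$infarct_half_width / pi * 100,
                   infarct_center_angle = p$infarct_center_angle,
                   infarct_half_width = p$infarct_half_width,
                   gains = list(t1 = p$t1_gain, ecv = p$ecv_gain,
                                fdg = p$fdg_gain),
                   remote = list(t1 = p$remote_t1, ecv = p$remote_ecv,
                                 fdg = p$remote_fdg),
                   blood = list(native_t1 = p$native_t1_blood,
                                post_t1 = p$post_t1_blood,
                                suv = p$blood_suv),
                   latent = NULL),
      params = p), class = "patient_record")
  })
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s: %dx%d grid, %d sectors, hct %.2f, infarct %.1f %%LV%s\n",
              x$id, nrow(x$maps$native_t1$data), ncol(x$maps$native_t1$data),
              x$n_sectors, x$hct, x$truth$infarct_size_pct_lv,
              if (is.null(x$molli)) "" else ", MOLLI series"))
  invisible(x)
}
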