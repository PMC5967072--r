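# Seeded phantom cohorts with the statistical structure the analysis layer
# assumes: per-patient infarct extent, central severity and systemic
# inflammation as latent variables; per-patient image maxima drawn around
# cohort means so that within-slice co-localization is perfect by
# construction while absolute maxima decouple across patients; blood-marker
# peaks as lognormal functions of the latents.
#
# Marker couplings are specified as the DESIGNED raw-scale Pearson
# correlation between the image maximum and the marker.  For a lognormal
# marker exp(mu + sigma*U) and a Gaussian image maximum whose z-score
# correlates with U at rho, corr(max, marker) = rho * sigma /
# sqrt(exp(sigma^2) - 1); the generator inverts this so the designed
# raw-scale correlation is met exactly.

#' Cohort-level generator parameters
#'
#' Defaults encode the study conditions of a 25-patient reperfused-AMI
#' cohort: infarct size 17.3 +/- 7.1 %LV, maximum / remote levels per
#' modality on the scale of max ECV 57.0 +/- 7.8 %, max native T1
#' 1432 +/- 101 ms, max FDG 2.62 +/- 0.53 SUV-LBM, marker peaks CK
#' 1806 +/- 930 U/l, CK-MB 211 +/- 124 U/l, troponin T 2.5 +/- 1.7 U/l,
#' leukocytes 12.8 +/- 4.3 G/l, monocytes 1.1 +/- 0.4 G/l, 24% apical
#' (16-sector) slices, heart rate 62 +/- 9 bpm, 88% male.
#'
#' @param n_patients cohort size (>= 3).
#' @param apical_fraction fraction of patients whose slice is apical
#'   (16 sectors); assignment is deterministic (evenly spread patient ids).
#' @param size_mean,size_sd infarct size (%LV) distribution.
#' @param max_ecv_mean,max_ecv_sd designed per-patient maximum ECV
#'   (fraction).
#' @param max_t1_mean,max_t1_sd designed maximum native T1 (ms).
#' @param max_fdg_mean,max_fdg_sd designed maximum FDG (SUV-LBM).
#' @param remote_ecv_mean,remote_ecv_sd,remote_t1_mean,remote_t1_sd,remote_fdg_mean,remote_fdg_sd
#'   per-patient remote levels (true tissue level, before measurement
#'   noise).
#' @param rho_extent_severity latent coupling between infarct extent and
#'   central severity.
#' @param r_size_ecv designed Pearson correlation between infarct size and
#'   maximum ECV (the extent/severity damage axis drives the ECV maximum).
#' @param rho_t1_inflammation latent coupling between systemic inflammation
#'   and the native-T1 (edema) maximum.
#' @param fdg_damage_loading,fdg_inflammation_loading loadings of the FDG
#'   maximum on the damage and inflammation axes (squares must sum to <= 1;
#'   the remainder is independent patient noise).
#' @param marker_links named list; each element
#'   `list(driver =, r =, mean =, sd =)` gives the marker's image driver
#'   (`"ecv"`, `"t1"` or `"fdg"`), its designed raw-scale Pearson
#'   correlation with that image maximum, and its lognormal mean/SD on the
#'   measurement scale.
#' @param min_elevation named list `t1`, `ecv`, `fdg`: smallest admissible
#'   sector-scale elevation of the maximum over the remote level (ms,
#'   fraction, SUV).  A per-patient maximum below its own remote level is
#'   not a maximum; the floors reflect the smallest max-to-remote
#'   separations compatible with the reported cohort ranges.
#' @param hct_mean,hct_sd hematocrit distribution (fraction).
#' @param heart_rate_mean,heart_rate_sd bpm.
#' @param male_fraction fraction of male patients (deterministic count).
#' @param weight_mean,weight_sd,height_mean,height_sd biometrics (kg, cm).
#' @param dose_mean,dose_sd,uptake_mean,uptake_sd injected dose (MBq) and
#'   injection-to-scan time (min).
#' @param include_molli generate MOLLI series per patient (needed for the
#'   T1-fitting pipeline path; off by default for statistical work).
#' @param phantom named list of [phantom_params()] overrides applied to
#'   every patient (e.g. `grid_size`, radii, `noise_sd`).
#' @return A validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 25L,
                          apical_fraction = 0.24,
                          size_mean = 17.3, size_sd = 7.1,
                          max_ecv_mean = 0.570, max_ecv_sd = 0.078,
                          max_t1_mean = 1432, max_t1_sd = 101,
                          max_fdg_mean = 2.62, max_fdg_sd = 0.53,
                          remote_ecv_mean = 0.278, remote_ecv_sd = 0.02,
                          remote_t1_mean = 1163, remote_t1_sd = 50,
                          remote_fdg_mean = 0.71, remote_fdg_sd = 0.15,
                          rho_extent_severity = 0.5,
                          r_size_ecv = 0.59,
                          rho_t1_inflammation = 0.8,
                          fdg_damage_loading = 0.4,
                          fdg_inflammation_loading = 0.4,
                          marker_links = list(
                            ck = list(driver = "ecv", r = 0.40,
                                      mean = 1806, sd = 930),
                            ck_mb = list(driver = "ecv", r = 0.60,
                                         mean = 211, sd = 124),
                            troponin_t = list(driver = "t1", r = 0.45,
                                              mean = 2.5, sd = 1.7),
                            leukocytes = list(driver = "t1", r = 0.43,
                                              mean = 12.8, sd = 4.3),
                            monocytes = list(driver = "t1", r = 0.60,
                                             mean = 1.1, sd = 0.4)),
                          min_elevation = list(t1 = 80, ecv = 0.06,
                                               fdg = 0.4),
                          hct_mean = 0.42, hct_sd = 0.03,
                          heart_rate_mean = 62, heart_rate_sd = 9,
                          male_fraction = 0.88,
                          weight_mean = 85, weight_sd = 12,
                          height_mean = 175, height_sd = 8,
                          dose_mean = 311, dose_sd = 72,
                          uptake_mean = 144, uptake_sd = 39,
                          include_molli = FALSE,
                          phantom = list()) {
  p <- as.list(environment())
  class(p) <- "cohort_params"
  validate_cohort_params(p)
}

validate_cohort_params <- function(p) {
  if (p$n_patients < 3) user_stopf("n_patients must be >= 3, got %d", p$n_patients)
  chk_num(p$apical_fraction, "apical_fraction", lo = 0, hi = 1)
  for (nm in c("rho_extent_severity", "rho_t1_inflammation"))
    chk_num(p[[nm]], nm, lo = -1, hi = 1)
  chk_num(abs(p$r_size_ecv), "abs(r_size_ecv)", lo = 0, hi = 1)
  if (p$fdg_damage_loading^2 + p$fdg_inflammation_loading^2 > 1)
    user_stopf("fdg loadings must satisfy damage^2 + inflammation^2 <= 1")
  for (nm in names(p$marker_links)) {
    l <- p$marker_links[[nm]]
    if (!all(c("driver", "r", "mean", "sd") %in% names(l)))
      user_stopf("marker link '%s' must name driver, r, mean, sd", nm)
    if (!l$driver %in% c("ecv", "t1", "fdg"))
      user_stopf("marker link '%s': unknown driver '%s'", nm, l$driver)
    if (l$mean <= 0 || l$sd <= 0)
      user_stopf("marker link '%s': mean and sd must be positive", nm)
  }
  p
}

# Analytic top-two sector-mean of the raised-cosine severity wedge: the
# angular integral of s over each sector bin divided by the bin width, for
# the bins the analysis uses (2*pi/n_sectors starting at the reference
# angle).  The biopsy maximum of a noise-free phantom is remote +
# gain * kappa, so the generator divides the designed elevation by kappa to
# place the designed maximum on the sector scale, independent of wedge
# width, position and sector count.
severity_sector_top2 <- function(half_width, n_sectors, center_angle,
                                 reference_angle = 0) {
  dtheta <- 2 * pi / n_sectors
  prim <- function(d) 0.5 * (d + half_width / pi * sin(pi * d / half_width))
  a <- reference_angle + dtheta * (seq_len(n_sectors) - 1) - center_angle
  a <- (a + pi) %% (2 * pi) - pi          # sector start, relative to center
  lo <- pmax(pmin(a, half_width), -half_width)
  hi <- pmax(pmin(a + dtheta, half_width), -half_width)
  kappa <- (prim(hi) - prim(lo)) / dtheta
  mean(sort(kappa, decreasing = TRUE)[1:2])
}

# latent coupling that yields a designed raw-scale Pearson correlation
# between a Gaussian image maximum and a lognormal marker
lognormal_latent_rho <- function(r_target, sigma) {
  if (r_target == 0) return(0)
  rho <- r_target * sqrt(exp(sigma^2) - 1) / sigma
  if (abs(rho) > 1)
    user_stopf("designed correlation %.2f is unattainable for lognormal sigma %.2f (needs |rho| = %.2f > 1)",
               r_target, sigma, abs(rho))
  rho
}

# deterministic, evenly spread assignment of k out of n patient ids
spread_ids <- function(n, k) {
  if (k <= 0) return(integer())
  unique(pmin(n, pmax(1L, round((seq_len(k) - 0.5) * n / k))))
}

#' Generate a seeded phantom cohort
#'
#' Draws per-patient latent variables (infarct extent, central severity,
#' systemic inflammation), designed image maxima and remote levels, blood
#' markers and biometrics, then builds one [make_phantom()] record per
#' patient.  Within-patient co-localization of the three image signals is
#' perfect by construction (a single severity field drives all three maps),
#' while the maxima decouple across patients according to the configured
#' couplings.  Every source of randomness flows from `seed`.
#'
#' @param n_patients number of patients (overrides `params$n_patients`).
#' @param params a [cohort_params()].
#' @param seed integer seed.
#' @return List of `patient_record`s (class `phantom_cohort`); each record
#'   carries its `markers` (named vector of peak values) and ground truth.
#' @export
make_cohort <- function(n_patients = NULL, params = cohort_params(), seed = 1L) {
  p <- validate_cohort_params(params)
  if (!is.null(n_patients)) {
    p$n_patients <- as.integer(n_patients)
    validate_cohort_params(p)
  }
  n <- p$n_patients

  with_seed(seed, {
    # latent axes
    z_extent <- stats::rnorm(n)
    z_sev <- p$rho_extent_severity * z_extent +
      sqrt(1 - p$rho_extent_severity^2) * stats::rnorm(n)
    z_infl <- stats::rnorm(n)
    # standardized damage axis (extent + severity)
    dmg_norm <- sqrt(2 + 2 * p$rho_extent_severity)
    z_dmg <- (z_extent + z_sev) / dmg_norm
    cor_dmg_extent <- (1 + p$rho_extent_severity) / dmg_norm

    # designed image maxima: ECV on the damage axis (so that its
    # correlation with infarct size is r_size_ecv), native T1 on the
    # inflammation axis, FDG a mixture of both plus independent noise
    rho_ecv_dmg <- p$r_size_ecv / cor_dmg_extent
    if (abs(rho_ecv_dmg) > 1)
      user_stopf("r_size_ecv %.2f unattainable for rho_extent_severity %.2f",
                 p$r_size_ecv, p$rho_extent_severity)
    zm_ecv <- rho_ecv_dmg * z_dmg + sqrt(1 - rho_ecv_dmg^2) * stats::rnorm(n)
    zm_t1 <- p$rho_t1_inflammation * z_infl +
      sqrt(1 - p$rho_t1_inflammation^2) * stats::rnorm(n)
    res_fdg <- sqrt(1 - p$fdg_damage_loading^2 - p$fdg_inflammation_loading^2)
    zm_fdg <- p$fdg_damage_loading * z_dmg +
      p$fdg_inflammation_loading * z_infl + res_fdg * stats::rnorm(n)

    size_pct <- pmin(45, pmax(6, p$size_mean + p$size_sd * z_extent))
    max_ecv <- p$max_ecv_mean + p$max_ecv_sd * zm_ecv
    max_t1 <- p$max_t1_mean + p$max_t1_sd * zm_t1
    max_fdg <- p$max_fdg_mean + p$max_fdg_sd * zm_fdg

    remote_ecv <- p$remote_ecv_mean + p$remote_ecv_sd * stats::rnorm(n)
    remote_t1 <- p$remote_t1_mean + p$remote_t1_sd * stats::rnorm(n)
    remote_fdg <- pmax(0.1, p$remote_fdg_mean + p$remote_fdg_sd * stats::rnorm(n))

    # markers: lognormal, linear in the latent image-maximum z-scores on
    # the log scale, with the latent coupling corrected so the designed
    # raw-scale Pearson correlation is met
    driver_z <- list(ecv = zm_ecv, t1 = zm_t1, fdg = zm_fdg)
    markers <- sapply(p$marker_links, function(l) {
      cv <- l$sd / l$mean
      sigma <- sqrt(log(1 + cv^2))
      mu <- log(l$mean) - sigma^2 / 2
      rho <- lognormal_latent_rho(l$r, sigma)
      u <- rho * driver_z[[l$driver]] + sqrt(1 - rho^2) * stats::rnorm(n)
      exp(mu + sigma * u)
    })
    markers <- matrix(markers, nrow = n,
                      dimnames = list(NULL, names(p$marker_links)))

    hct <- pmin(0.55, pmax(0.25, p$hct_mean + p$hct_sd * stats::rnorm(n)))
    hr <- pmin(110, pmax(40, p$heart_rate_mean + p$heart_rate_sd * stats::rnorm(n)))
    weight <- pmax(45, p$weight_mean + p$weight_sd * stats::rnorm(n))
    height <- pmin(210, pmax(145, p$height_mean + p$height_sd * stats::rnorm(n)))
    dose <- pmax(100, p$dose_mean + p$dose_sd * stats::rnorm(n))
    uptake <- pmax(45, p$uptake_mean + p$uptake_sd * stats::rnorm(n))
    center_angle <- stats::runif(n, 0, 2 * pi)
    patient_seed <- sample.int(.Machine$integer.max - 1L, n)

    apical <- spread_ids(n, round(p$apical_fraction * n))
    male <- spread_ids(n, round(p$male_fraction * n))

    records <- vector("list", n)
    for (i in seq_len(n)) {
      ns_i <- if (i %in% apical) 16L else 32L
      hw_i <- size_pct[i] / 100 * pi
      # sector-averaging attenuation of this patient's wedge; dividing the
      # designed elevation by it makes the biopsy maximum land on the
      # designed value (the peak pixel elevation is gain, capped so ECV
      # stays physical on narrow apical wedges)
      kappa_i <- severity_sector_top2(hw_i, ns_i, center_angle[i])
      args <- list(
        n_sectors = ns_i,
        infarct_center_angle = center_angle[i],
        infarct_half_width = hw_i,
        remote_t1 = remote_t1[i], remote_ecv = remote_ecv[i],
        remote_fdg = remote_fdg[i],
        t1_gain = max(p$min_elevation$t1, max_t1[i] - remote_t1[i]) / kappa_i,
        ecv_gain = min(max(p$min_elevation$ecv,
                           max_ecv[i] - remote_ecv[i]) / kappa_i,
                       0.95 - remote_ecv[i]),
        fdg_gain = max(p$min_elevation$fdg, max_fdg[i] - remote_fdg[i]) / kappa_i,
        hematocrit = hct[i], heart_rate = hr[i],
        weight = weight[i], height = height[i],
        sex = if (i %in% male) "male" else "female",
        injected_dose = dose[i], uptake_min = uptake[i],
        seed = patient_seed[i])
      args <- utils::modifyList(args, p$phantom)
      rec <- make_phantom(do.call(phantom_params, args),
                          include_molli = p$include_molli)
      rec$id <- sprintf("P%02d", i)
      rec$markers <- markers[i, ]
      rec$truth$latent <- list(
        infarct_extent = size_pct[i] / 100,
        central_severity = stats::pnorm(z_sev[i]),
        inflammation = stats::pnorm(z_infl[i]))
      rec$truth$designed_max <- list(ecv = max_ecv[i], t1 = max_t1[i],
                                     fdg = max_fdg[i])
      records[[i]] <- rec
    }
    structure(records, class = "phantom_cohort")
  })
}

#' @export
print.phantom_cohort <- function(x, ...) {
  ns <- vapply(x, function(r) r$n_sectors, integer(1))
  cat(sprintf("<phantom_cohort> %d patients (%d apical / 16-sector)\n",
              length(x), sum(ns == 16L)))
  invisible(x)
}

#' Marker and ground-truth table of a cohort
#'
#' @param cohort a list of `patient_record`s from [make_cohort()].
#' @return Data frame with one row per patient: id, blood-marker peaks,
#'   ground-truth infarct size (%LV) and latent variables.
#' @export
cohort_markers <- function(cohort) {
  do.call(rbind, lapply(cohort, function(r) {
    data.frame(patient = r$id, t(r$markers),
               infarct_size_pct_lv = r$truth$infarct_size_pct_lv,
               extent = r$truth$latent$infarct_extent %||% NA_real_,
               severity = r$truth$latent$central_severity %||% NA_real_,
               inflammation = r$truth$latent$inflammation %||% NA_real_,
               row.names = NULL)
  }))
}
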