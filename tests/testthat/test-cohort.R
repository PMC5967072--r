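# Cohort generator: determinism, allocation rules, designed couplings

test_that("same seed reproduces identical marker tables and records", {
  a <- make_cohort(10, cohort_params(), seed = 1)
  b <- make_cohort(10, cohort_params(), seed = 1)
  expect_identical(cohort_markers(a), cohort_markers(b))
  expect_identical(a[[4]]$maps$native_t1$data, b[[4]]$maps$native_t1$data)
})

test_that("apical (16-sector) slices match the configured fraction exactly", {
  co <- make_cohort(25, cohort_params(), seed = 2)
  ns <- vapply(co, function(r) r$n_sectors, integer(1))
  expect_equal(sum(ns == 16L), round(0.24 * 25))   # 6 of 25
  co2 <- make_cohort(10, cohort_params(apical_fraction = 0.5), seed = 2)
  ns2 <- vapply(co2, function(r) r$n_sectors, integer(1))
  expect_equal(sum(ns2 == 16L), 5L)
})

test_that("marker peaks are strictly positive with the designed scale", {
  co <- make_cohort(40, cohort_params(), seed = 3)
  mk <- cohort_markers(co)
  for (nm in c("ck", "ck_mb", "troponin_t", "leukocytes", "monocytes"))
    expect_true(all(mk[[nm]] > 0))
  # lognormal scale sanity (means within a loose factor of the design)
  expect_gt(mean(mk$ck), 1806 / 2)
  expect_lt(mean(mk$ck), 1806 * 2)
  expect_true(all(mk$infarct_size_pct_lv > 0 & mk$infarct_size_pct_lv < 50))
})

test_that("lognormal latent coupling yields the designed raw-scale correlation", {
  # independent Monte-Carlo oracle of the analytic correction used by the
  # generator: corr(z, exp(mu + sigma*u)) with u = rho*z + ... must hit the
  # requested raw-scale target
  set.seed(99)
  n <- 2e5
  sigma <- sqrt(log(1 + (124 / 211)^2))    # CK-MB dispersion
  rho <- cmrpet:::lognormal_latent_rho(0.6, sigma)
  z <- rnorm(n)
  u <- rho * z + sqrt(1 - rho^2) * rnorm(n)
  marker <- exp(log(211) - sigma^2 / 2 + sigma * u)
  expect_equal(cor(z, marker), 0.6, tolerance = 0.01)
  expect_equal(cmrpet:::lognormal_latent_rho(0, sigma), 0)
  expect_error(cmrpet:::lognormal_latent_rho(0.99, 2), "unattainable")
})

test_that("designed couplings surface in the generated cohort truths", {
  co <- make_cohort(600, cohort_params(phantom = list(grid_size = 47,
                                                      endo_radius = 8,
                                                      epi_radius = 14)),
                    seed = 5)
  mk <- cohort_markers(co)
  dmax <- t(vapply(co, function(r) unlist(r$truth$designed_max), numeric(3)))
  # max ECV vs CK-MB and infarct size; max T1 vs monocytes (design 0.6 / 0.59 / 0.6)
  expect_equal(cor(dmax[, "ecv"], mk$ck_mb), 0.6, tolerance = 0.1)
  expect_equal(cor(dmax[, "ecv"], mk$infarct_size_pct_lv), 0.59, tolerance = 0.1)
  expect_equal(cor(dmax[, "t1"], mk$monocytes), 0.6, tolerance = 0.1)
  # null couplings decorrelate by construction
  co0 <- make_cohort(600, cohort_params(
    r_size_ecv = 0, fdg_damage_loading = 0, fdg_inflammation_loading = 0,
    marker_links = list(ck_mb = list(driver = "ecv", r = 0,
                                     mean = 211, sd = 124)),
    phantom = list(grid_size = 47, endo_radius = 8, epi_radius = 14)),
    seed = 6)
  mk0 <- cohort_markers(co0)
  dmax0 <- t(vapply(co0, function(r) unlist(r$truth$designed_max), numeric(3)))
  expect_lt(abs(cor(dmax0[, "ecv"], mk0$ck_mb)), 0.1)
  expect_lt(abs(cor(dmax0[, "ecv"], mk0$infarct_size_pct_lv)), 0.1)
})

test_that("cohort validation guards degenerate configurations", {
  expect_error(make_cohort(2), ">= 3")
  expect_error(cohort_params(fdg_damage_loading = 0.9,
                             fdg_inflammation_loading = 0.9), "loadings")
  expect_error(cohort_params(marker_links = list(bad = list(driver = "x",
                                                            r = 0, mean = 1,
                                                            sd = 1))),
               "driver")
})
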