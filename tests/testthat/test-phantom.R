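# Synthetic phantom: construction guarantees, determinism, RNG hygiene

test_that("zero gains and zero noise give a flat annulus at remote values", {
  rec <- make_phantom(quiet_phantom(t1_gain = 0, ecv_gain = 0, fdg_gain = 0,
                                    seed = 1))
  myo <- rec$maps$native_t1$mask
  expect_true(all(rec$maps$native_t1$data[myo] == rec$truth$remote$t1))
  expect_true(all(rec$truth$ecv[myo] == rec$truth$remote$ecv))
  expect_true(all(rec$truth$suv[myo] == rec$truth$remote$fdg))
})

test_that("the mid-wall pixel on the infarct center ray carries remote + gain exactly", {
  p <- quiet_phantom(seed = 3)            # center angle 0, odd grid
  rec <- make_phantom(p)
  ctr <- (p$grid_size + 1) / 2
  mid_r <- round((p$endo_radius + p$epi_radius) / 2)
  px <- cbind(ctr + mid_r, ctr)
  expect_true(rec$maps$native_t1$mask[px])
  expect_equal(rec$truth$ecv[px], p$remote_ecv + p$ecv_gain)
  expect_equal(rec$truth$native_t1[px], p$remote_t1 + p$t1_gain)
  expect_equal(rec$truth$suv[px], p$remote_fdg + p$fdg_gain)
  # designed infarct size is the wedge fraction of the annulus
  expect_equal(rec$truth$infarct_size_pct_lv, p$infarct_half_width / pi * 100)
})

test_that("ground-truth ECV is recomputable from the generated T1 pairs", {
  rec <- make_phantom(quiet_phantom(seed = 11))
  myo <- rec$maps$native_t1$mask
  ecv <- compute_ecv(rec$truth$native_t1[myo], rec$truth$post_t1[myo],
                     list(native_t1_blood = rec$truth$blood$native_t1,
                          post_t1_blood = rec$truth$blood$post_t1),
                     rec$hct)
  expect_lt(max(abs(ecv - rec$truth$ecv[myo])), 1e-10)
})

test_that("same seed gives bit-identical records; phantom RNG does not leak", {
  a <- make_phantom(phantom_params(seed = 7), include_molli = TRUE)
  b <- make_phantom(phantom_params(seed = 7), include_molli = TRUE)
  expect_identical(a, b)

  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(make_phantom(phantom_params(seed = 99)))
  expect_identical(rnorm(1), before)
})

test_that("maps share one grid and one myocardial mask; geometry is validated", {
  rec <- make_phantom(quiet_phantom(seed = 1))
  for (m in rec$maps) {
    expect_identical(dim(m$data), dim(rec$maps$native_t1$data))
    expect_identical(m$mask, rec$maps$native_t1$mask)
  }
  expect_error(phantom_params(endo_radius = 30, epi_radius = 20), "annulus")
  expect_error(phantom_params(epi_radius = 60, grid_size = 95), "annulus")
  expect_error(phantom_params(hematocrit = 1.2), "hematocrit")
  expect_error(phantom_params(n_sectors = 12), "16 or 32")
})

test_that("MOLLI series are generated from the true T1 maps via the signal model", {
  rec <- make_phantom(quiet_phantom(seed = 4), include_molli = TRUE)
  myo <- rec$maps$native_t1$mask
  px <- which(myo)[25]
  ti <- rec$molli$native$ti
  expected <- molli_signal(ti, rec$truth$native_t1[px])
  got <- vapply(seq_along(ti), function(t) rec$molli$native$data[, , t][px],
                numeric(1))
  expect_equal(got, expected, tolerance = 1e-12)
  # blood pixels carry the blood T1 recovery so the cavity ROI can be fitted
  bpx <- which(rec$blood_roi$mask)[1]
  got_b <- vapply(seq_along(ti), function(t) rec$molli$post$data[, , t][bpx],
                  numeric(1))
  expect_equal(got_b, molli_signal(ti, rec$truth$blood$post_t1),
               tolerance = 1e-12)
})
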