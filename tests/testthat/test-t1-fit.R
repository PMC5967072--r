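# Pixelwise T1 fitting: exactness, invariants, degenerate inputs, map path

ti_62 <- sort(molli_ti(molli_scheme(), heart_rate = 62))

test_that("noiseless curves are recovered exactly with consistent Look-Locker algebra", {
  for (t1 in c(250, 480, 900, 1430, 1900)) {
    s <- molli_signal(ti_62, t1)
    fit <- fit_t1_pixel(ti_62, s)
    expect_true(fit$ok)
    expect_rel_equal(fit$t1, t1, 1e-6)
    # definitional invariant of the Look-Locker correction
    expect_rel_equal(fit$t1, fit$t1_star * (fit$b / fit$a - 1), 1e-9)
    expect_gt(fit$b / fit$a, 1)
    # flips = number of samples before the signal null
    expect_equal(fit$polarity_flips, sum(ti_62 < t1 * log(2)))
  }
})

test_that("degenerate and invalid inputs are flagged, never crash", {
  expect_false(fit_t1_pixel(ti_62, rep(5, length(ti_62)))$ok)
  f <- fit_t1_pixel(ti_62, c(NA, molli_signal(ti_62, 600)[-1]))
  expect_false(f$ok)
  expect_match(f$reason, "non-finite")
  expect_error(fit_t1_pixel(ti_62[1:4], 1:4), "at least 5")
  expect_error(fit_t1_pixel(rev(ti_62), molli_signal(ti_62, 600)), "sorted")
  expect_error(fit_t1_pixel(ti_62 - 200, molli_signal(ti_62, 600)), "positive")
})

test_that("fit is scale-equivariant in signal and time units", {
  s <- molli_signal(ti_62, 700)
  base <- fit_t1_pixel(ti_62, s)
  for (c_sig in c(0.01, 7, 1e4)) {
    f <- fit_t1_pixel(ti_62, c_sig * s)
    expect_rel_equal(f$t1, base$t1, 1e-6)
  }
  for (c_t in c(0.5, 3)) {
    f <- fit_t1_pixel(ti_62 * c_t, molli_signal(ti_62 * c_t, 700 * c_t))
    expect_rel_equal(f$t1, 700 * c_t, 1e-6)
    expect_rel_equal(f$t1_star, base$t1_star * c_t, 1e-5)
  }
})

test_that("polarity restoration never increases the residual over the no-flip fit", {
  set.seed(301)
  for (rep in 1:20) {
    t1 <- runif(1, 250, 1700)
    y <- abs(molli_signal(ti_62, t1) + rnorm(length(ti_62), 0, 3))
    fit <- fit_t1_pixel(ti_62, y)
    noflip <- stats::optimize(function(t1s) vp_rss_fixed_flip(ti_62, y, 0, t1s),
                              c(min(ti_62) / 20, max(ti_62) * 3))$objective
    expect_lte(fit$residual_rms^2 * length(ti_62), noflip + 1e-8)
  }
})

test_that("noisy fits agree with an exhaustive grid-search oracle", {
  set.seed(77)
  n_checked <- 0
  for (rep in 1:12) {
    t1 <- runif(1, 300, 1500)
    y <- abs(molli_signal(ti_62, t1) + rnorm(length(ti_62), 0, 2))
    fit <- fit_t1_pixel(ti_62, y)
    oracle <- grid_search_t1_oracle(ti_62, y)
    expect_rel_equal(fit$t1, oracle$t1, 0.03)
    expect_lte(fit$residual_rms^2 * length(ti_62), oracle$rss + 1e-8)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 12)
})

test_that("map fitting reproduces ground truth and isolates artifact pixels", {
  rec <- make_phantom(quiet_phantom(seed = 5), include_molli = TRUE)
  myo <- rec$maps$native_t1$mask
  t1map <- suppressMessages(fit_t1_map(rec$molli$native, myo))
  expect_true(all(t1map$mask == myo))
  expect_rel_equal(t1map$data[myo], rec$truth$native_t1[myo], 1e-6)

  # one artifact pixel: excluded, neighbours untouched
  bad <- which(myo)[10]
  rec$molli$native$data[, , 3][bad] <- NaN
  t1map2 <- suppressMessages(fit_t1_map(rec$molli$native, myo))
  expect_false(t1map2$mask[bad])
  expect_equal(attr(t1map2, "n_excluded"), 1L)
  others <- which(myo & t1map2$mask)
  expect_rel_equal(t1map2$data[others], t1map$data[others], 1e-9)

  expect_error(fit_t1_map(rec$molli$native, myo & FALSE), "empty mask")
})
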