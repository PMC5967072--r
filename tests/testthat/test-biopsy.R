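# Imaging-biopsy statistics: max, remote, argmax distances

test_that("maximum is the mean of the two largest with deterministic ties", {
  mx <- max_biopsy(1:32)
  expect_equal(mx$value, 31.5)
  expect_equal(mx$sectors, c(31L, 32L))
  tie <- max_biopsy(rep(4.2, 16))
  expect_equal(tie$value, 4.2)
  expect_equal(tie$sectors, c(1L, 2L))       # ties to lower ids
  expect_error(max_biopsy(c(1, NA, NA)), "at least 2")
})

test_that("max is permutation-invariant up to ties and ignores excluded sectors", {
  set.seed(8)
  v <- runif(32)
  perm <- sample(32)
  expect_equal(max_biopsy(v)$value, max_biopsy(v[perm])$value)
  # excluding the top sector moves the max down deterministically
  ex <- rep(FALSE, 32)
  ex[which.max(v)] <- TRUE
  expect_equal(max_biopsy(v, ex)$value,
               mean(sort(v[!ex], decreasing = TRUE)[1:2]))
  # adding excluded sectors never changes the result
  expect_equal(max_biopsy(c(v, 99, 99), c(ex, TRUE, TRUE))$value,
               max_biopsy(v, ex)$value)
})

test_that("remote selection matches the modular-arithmetic oracle for all argmax positions", {
  for (n in c(16L, 32L)) {
    v <- rep(1, n)
    for (am in seq_len(n)) {
      got <- remote_selection(v, argmax = am, n_sectors = n)$sectors
      expect_identical(got, remote_ids_oracle(am, n))
      # distal invariant: every remote id at circular distance >= n/2 - 2
      expect_true(all(circ_dist_pkg(got, am, n) >= n / 2 - 2))
    }
  }
  # worked cases
  expect_identical(remote_selection(rep(1, 32), argmax = 1)$sectors,
                   c(16L, 17L, 18L))
  expect_identical(remote_selection(rep(1, 16), argmax = 9)$sectors,
                   c(1L, 2L, 16L))
})

test_that("excluded remote candidates are replaced by the next-most-distal valid sector", {
  ex <- rep(FALSE, 32)
  ex[17] <- TRUE
  r <- remote_selection(rep(1, 32), ex, argmax = 1, n_sectors = 32)
  expect_length(r$sectors, 3)
  expect_identical(r$sectors, c(15L, 16L, 18L))
  # remote value averages the three chosen sectors
  v <- seq_len(32)
  r2 <- remote_selection(v, argmax = which.max(v), n_sectors = 32)
  expect_equal(r2$value, mean(v[r2$sectors]))
  ex_all <- rep(TRUE, 32)
  ex_all[1] <- FALSE
  expect_error(remote_selection(rep(1, 32), ex_all, argmax = 1,
                                n_sectors = 32), "remote")
})

test_that("argmax distance is the circular metric", {
  expect_equal(argmax_distance(2, 31, 32), 3)
  expect_equal(argmax_distance(9, 9, 16), 0)
  expect_equal(argmax_distance(1, 17, 32), 16)
  expect_equal(argmax_distance(1, 16, 16), 1)
})

test_that("phantom biopsy locates the wedge and co-localizes across modalities", {
  rec <- make_phantom(quiet_phantom(infarct_center_angle = pi / 3, seed = 6))
  myo <- rec$maps$native_t1$mask
  sm <- build_sectors(rec$contours$endo, rec$contours$epi, 32,
                      grid_dim = dim(myo))
  tbl <- sector_table(list(ecv = scalar_map(rec$truth$ecv, myo, "ecv", "fraction"),
                           native_t1 = scalar_map(rec$truth$native_t1, myo),
                           fdg = scalar_map(rec$truth$suv, myo)), sm)
  bs <- biopsy_summary(tbl)
  # the two max sectors are those nearest the infarct center angle
  center_sector <- floor((pi / 3) / (2 * pi / 32)) + 1
  for (i in seq_len(nrow(bs)))
    expect_lte(argmax_distance(bs$argmax[i], center_sector, 32), 1)
  d <- argmax_distances(bs)
  expect_true(all(d$distance == 0))        # perfect co-localization, no noise
  expect_setequal(d$pair, c("ecv/fdg", "ecv/native_t1", "fdg/native_t1"))
})
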