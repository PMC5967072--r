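# Centerline sector segmentation: partition axioms, symmetry, extraction

test_that("sector labels exactly partition the annulus on circular and elliptical geometry", {
  rec <- make_phantom(quiet_phantom(seed = 1))
  myo <- rec$maps$native_t1$mask
  sm <- build_sectors(rec$contours$endo, rec$contours$epi, 32,
                      grid_dim = dim(myo))
  expect_identical(sm$labels > 0L, myo)                 # union = annulus
  expect_true(all(sm$labels[myo] %in% 1:32))            # every pixel labeled once
  expect_equal(sort(unique(sm$labels[myo])), 1:32)

  ctr <- c(31, 31)
  endo <- ellipse_contour(ctr, 9, 13)
  epi <- ellipse_contour(ctr, 17, 22)
  sm_e <- build_sectors(endo, epi, 16, grid_dim = c(61, 61))
  myo_e <- sm_e$labels > 0L
  expect_gt(sum(myo_e), 200)
  expect_equal(sort(unique(sm_e$labels[myo_e])), 1:16)
})

test_that("ideal circular annulus sector areas are equal within 2 percent", {
  ctr <- c(128.5, 128.5)
  endo <- circle_contour(ctr, 55)
  epi <- circle_contour(ctr, 95)
  # generic reference angle: with boundaries exactly along pixel rows
  # (reference 0) the half-open tie convention assigns whole pixel rows to
  # one side, a measure-zero degeneracy the geometric expectation excludes
  for (n_sec in c(16L, 32L)) {
    sm <- build_sectors(endo, epi, n_sec, reference_angle = 0.1,
                        grid_dim = c(256, 256))
    counts <- tabulate(sm$labels[sm$labels > 0], n_sec)
    expect_lt(max(abs(counts - mean(counts))) / mean(counts), 0.02)
    sm0 <- build_sectors(endo, epi, n_sec, grid_dim = c(256, 256))
    counts0 <- tabulate(sm0$labels[sm0$labels > 0], n_sec)
    expect_lt(max(abs(counts0 - mean(counts0))) / mean(counts0), 0.04)
  }
})

test_that("rotating the reference angle by one sector permutes labels cyclically", {
  rec <- make_phantom(quiet_phantom(seed = 2))
  myo <- rec$maps$native_t1$mask
  for (n_sec in c(16L, 32L)) {
    sm0 <- build_sectors(rec$contours$endo, rec$contours$epi, n_sec,
                         reference_angle = 0, grid_dim = dim(myo))
    sm1 <- build_sectors(rec$contours$endo, rec$contours$epi, n_sec,
                         reference_angle = 2 * pi / n_sec, grid_dim = dim(myo))
    shifted <- ifelse(sm1$labels > 0L, sm1$labels %% n_sec + 1L, 0L)
    expect_identical(shifted, sm0$labels)
    # sector value multisets unchanged under the relabeling
    v0 <- extract_sector_values(rec$maps$native_t1, sm0)$value
    v1 <- extract_sector_values(rec$maps$native_t1, sm1)$value
    expect_equal(sort(v0), sort(v1), tolerance = 1e-12)
  }
})

test_that("sector ids increase counter-clockwise from the reference angle", {
  rec <- make_phantom(quiet_phantom(seed = 2))
  myo <- rec$maps$native_t1$mask
  sm <- build_sectors(rec$contours$endo, rec$contours$epi, 32,
                      grid_dim = dim(myo))
  # monotone CCW: sector of the centerline samples is non-decreasing 1..32
  expect_identical(sm$sector_of_sample[1], 1L)
  expect_true(all(diff(sm$sector_of_sample) >= 0))
  expect_equal(max(sm$sector_of_sample), 32L)
  # and agrees with the pure angular bin up to the half-sample tolerance
  idx <- which(myo)
  ctr <- sm$centroid
  px_ang <- atan2((idx - 1) %/% nrow(myo) + 1 - ctr[2],
                  (idx - 1) %% nrow(myo) + 1 - ctr[1])
  expected <- floor(((px_ang %% (2 * pi)) / (2 * pi)) * 32) + 1
  expect_true(all(circ_dist_pkg(sm$labels[idx], expected, 32) <= 1))
  expect_gt(mean(sm$labels[idx] == expected), 0.9)
})

test_that("extraction: constant maps, artifact exclusion and co-localized propagation", {
  rec <- make_phantom(quiet_phantom(seed = 3))
  myo <- rec$maps$native_t1$mask
  sm <- build_sectors(rec$contours$endo, rec$contours$epi, 32,
                      grid_dim = dim(myo))
  const <- scalar_map(matrix(7.5, nrow(myo), ncol(myo)), myo)
  ev <- extract_sector_values(const, sm)
  expect_true(all(ev$value == 7.5))
  expect_false(any(ev$excluded))

  # artifact wiping one sector excludes it in all modalities
  art <- rec$maps$native_t1
  art$mask[sm$labels == 5L] <- FALSE
  tbl <- sector_table(list(ecv = scalar_map(rec$truth$ecv, myo,
                                            "ecv", "fraction"),
                           native_t1 = art,
                           fdg = scalar_map(rec$truth$suv, myo)),
                      sm, patient = "P01")
  ex5 <- tbl[tbl$sector == 5L, ]
  expect_true(all(ex5$excluded))
  expect_setequal(unique(tbl$excluded[tbl$sector != 5L]), FALSE)
  # ECV rendered in percent in the tidy table
  expect_gt(min(tbl$value[tbl$modality == "ecv" & !tbl$excluded]), 20)
})

test_that("wedge sector means match the truth field exactly and its angular integral approximately", {
  rec <- make_phantom(quiet_phantom(seed = 4))
  myo <- rec$maps$native_t1$mask
  sm <- build_sectors(rec$contours$endo, rec$contours$epi, 32,
                      grid_dim = dim(myo))
  sev_means <- extract_sector_values(scalar_map(rec$truth$severity, myo), sm)$value
  ecv_means <- extract_sector_values(scalar_map(rec$truth$ecv, myo,
                                                "ecv", "fraction"), sm)$value
  expect_lt(max(abs(ecv_means - (0.278 + 0.292 * sev_means))), 1e-10)

  # analytic angular integral of the raised cosine over each sector
  hw <- rec$truth$infarct_half_width
  prim <- function(d) 0.5 * (d + hw / pi * sin(pi * d / hw))  # integral of s
  edges <- 2 * pi * (0:32) / 32
  analytic <- vapply(seq_len(32), function(k) {
    lo <- edges[k] - rec$truth$infarct_center_angle
    hi <- edges[k + 1] - rec$truth$infarct_center_angle
    lo <- pmax(pmin(lo, hw), -hw)
    hi <- pmax(pmin(hi, hw), -hw)
    (prim(hi) - prim(lo)) / (2 * pi / 32)
  }, numeric(1))
  wedge <- analytic > 0.05
  expect_lt(max(abs(sev_means[wedge] - analytic[wedge])), 0.02)
})

test_that("geometry errors are reported: enclosure, star-shape, grid mismatch", {
  ctr <- c(31, 31)
  expect_error(build_sectors(circle_contour(ctr, 15), circle_contour(ctr, 10),
                             32, grid_dim = c(61, 61)), "enclose")
  bowtie <- cbind(c(20, 42, 20, 42, 31, 25, 31, 37),
                  c(20, 42, 42, 20, 25, 31, 37, 31))
  expect_error(build_sectors(circle_contour(ctr, 8), bowtie, 32,
                             grid_dim = c(61, 61)))
  rec <- make_phantom(quiet_phantom(seed = 1))
  sm <- build_sectors(rec$contours$endo, rec$contours$epi, 32,
                      grid_dim = dim(rec$maps$native_t1$data))
  expect_error(extract_sector_values(scalar_map(matrix(1, 4, 4)), sm), "grid")
})
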