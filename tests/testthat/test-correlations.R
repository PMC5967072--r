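# Between-/within-subject correlations, slopes, marker correlations

test_that("between-subject correlation works on per-patient means with k-2 df", {
  # shared profile scaled per patient in both modalities -> r = 1
  prof <- c(1, 2, 5, 3)
  d <- do.call(rbind, lapply(1:5, function(i)
    data.frame(patient = i, x = i * prof, y = (i + 2) * prof)))
  b <- between_subject_corr(d)
  expect_equal(b$r, 1, tolerance = 1e-12)
  expect_equal(b$df, 3)
  expect_equal(b$n, 5)
  # invariant to permuting sectors within patients
  d2 <- d
  d2$x <- unlist(lapply(split(d$x, d$patient), sample))
  expect_equal(between_subject_corr(d2)$r, b$r)
  expect_error(between_subject_corr(d[d$patient <= 2, ]), ">= 3 patients")
  d3 <- d
  d3$x <- 1
  expect_error(between_subject_corr(d3), "zero variance")
})

test_that("within-subject correlation strips per-patient offsets (ANCOVA reading)", {
  set.seed(10)
  d <- do.call(rbind, lapply(1:4, function(i) {
    x <- rnorm(6)
    data.frame(patient = i, x = x, y = 100 * i + 3 * x)  # own intercept, shared slope
  }))
  w <- within_subject_corr(d)
  expect_equal(w$r, 1, tolerance = 1e-9)
  expect_equal(w$df, 24 - 4 - 1)
  # invariant to adding any per-patient constant to x or y
  d_shift <- d
  d_shift$x <- d$x + 1000 * as.integer(d$patient)
  d_shift$y <- d$y - 77 * as.integer(d$patient)
  expect_equal(within_subject_corr(d_shift)$r, w$r, tolerance = 1e-9)
})

test_that("within-subject r, p, df match the dummy-variable regression oracle to 1e-10", {
  set.seed(55)
  for (rep in 1:10) {
    d <- data.frame(patient = rep(paste0("p", 1:3), each = 4),
                    x = rnorm(12), y = rnorm(12))
    w <- within_subject_corr(d)
    o <- ancova_oracle(d)
    expect_equal(w$r, o$r, tolerance = 1e-10)
    expect_equal(w$p, o$p, tolerance = 1e-10)
    expect_equal(w$df, o$df)
  }
})

test_that("constructed orthogonal within-patient deviations give r = 0", {
  d <- do.call(rbind, lapply(1:3, function(i)
    data.frame(patient = i, x = c(0, 1, 0, 1) + 10 * i,
               y = c(0, 0, 1, 1) - 3 * i)))
  expect_equal(within_subject_corr(d)$r, 0, tolerance = 1e-12)
})

test_that("degenerate patients are dropped with a warning, not silently used", {
  d <- rbind(data.frame(patient = 1, x = c(1, 1, 1), y = c(1, 2, 3)),
             data.frame(patient = 2, x = c(1, 2, 3), y = c(2, 4, 7)),
             data.frame(patient = 3, x = c(0, 2, 5), y = c(1, 3, 9)))
  expect_warning(w <- within_subject_corr(d), "dropping 1")
  expect_equal(w$n, 6)
  d_all_bad <- d[d$patient == 1, ]
  expect_error(suppressWarnings(within_subject_corr(d_all_bad)), "usable")
})

test_that("per-subject slopes recover the designed lines and flag short series", {
  d <- rbind(data.frame(patient = "a", x = c(0, 1, 2, 3), y = 2 * c(0, 1, 2, 3) + 1),
             data.frame(patient = "b", x = c(0, 2), y = c(5, 6)))
  s <- per_subject_slopes(d)
  expect_equal(s$slope[s$patient == "a"], 2)
  expect_equal(s$intercept[s$patient == "a"], 1)
  expect_true(s$flagged[s$patient == "b"])
  expect_true(is.na(s$slope[s$patient == "b"]))
})

test_that("null between-subject correlation matches its reference distribution", {
  set.seed(404)
  k <- 8
  r_crit <- {
    tc <- qt(0.975, k - 2)
    tc / sqrt(tc^2 + k - 2)
  }
  rs <- replicate(200, {
    d <- data.frame(patient = rep(1:k, each = 6),
                    x = rep(rnorm(k), each = 6) + rnorm(6 * k, 0, 0.2),
                    y = rep(rnorm(k), each = 6) + rnorm(6 * k, 0, 0.2))
    between_subject_corr(d)$r
  })
  expect_lt(abs(mean(rs)), 0.09)                  # centered on zero
  rej <- mean(abs(rs) > r_crit)
  expect_gt(rej, 0.005)                           # calibrated 5% level
  expect_lt(rej, 0.12)
})

test_that("marker correlations: identity, pairwise deletion, sparse cells, Bonferroni", {
  img <- data.frame(patient = paste0("P", 1:6), max_ecv = c(40, 45, 50, 55, 60, 65),
                    max_t1 = c(1300, 1350, 1420, 1380, 1500, 1460))
  mk <- data.frame(patient = paste0("P", 1:6), ck_mb = c(40, 45, 50, 55, 60, 65),
                   monocytes = c(1.1, NA, 0.9, 1.4, 1.0, 1.3))
  mc <- marker_correlations(img, mk)
  expect_equal(mc$r[mc$image == "max_ecv" & mc$marker == "ck_mb"], 1,
               tolerance = 1e-12)
  expect_equal(mc$n[mc$image == "max_ecv" & mc$marker == "monocytes"], 5)
  expect_equal(mc$n[mc$image == "max_ecv" & mc$marker == "ck_mb"], 6)

  mk_sparse <- data.frame(patient = paste0("P", 1:6),
                          troponin_t = c(1, 2, NA, NA, NA, NA))
  mc2 <- marker_correlations(img, mk_sparse)
  expect_true(all(is.na(mc2$r)))
  expect_equal(mc2$n, rep(2L, 2))

  mcb <- marker_correlations(img, mk, bonferroni = TRUE)
  expect_equal(mcb$p, pmin(1, mc$p * sum(!is.na(mc$p))))
})
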