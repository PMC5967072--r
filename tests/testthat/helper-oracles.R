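# Independent oracles and small fixtures, built in code.

# Brute-force grid-search oracle for the MOLLI fit: exhaustive search over
# (A, B/A, T1*) grids and all polarity-flip counts, no shared code with the
# package's variable-projection fitter.
grid_search_t1_oracle <- function(ti, signals,
                                  a_grid = NULL, ratio_grid = NULL,
                                  t1s_grid = NULL) {
  if (is.null(a_grid)) {
    a0 <- max(signals)
    a_grid <- seq(0.7 * a0, 1.3 * a0, length.out = 40)
  }
  if (is.null(ratio_grid)) ratio_grid <- seq(1.5, 2.5, length.out = 40)
  if (is.null(t1s_grid))
    t1s_grid <- exp(seq(log(min(ti) / 10), log(max(ti) * 2), length.out = 120))
  n <- length(ti)
  best <- list(rss = Inf)
  for (k in 0:(n - 1)) {
    y <- signals
    if (k > 0) y[seq_len(k)] <- -y[seq_len(k)]
    for (a in a_grid) for (rt in ratio_grid) {
      b <- a * rt
      pred <- outer(-ti, 1 / t1s_grid)       # n x n_t1s
      pred <- a - b * exp(pred)
      rss <- colSums((y - pred)^2)
      j <- which.min(rss)
      if (rss[j] < best$rss)
        best <- list(rss = rss[j], a = a, b = b, t1_star = t1s_grid[j],
                     t1 = t1s_grid[j] * (rt - 1), k = k)
    }
  }
  best
}

# one-dimensional residual of the inversion-recovery model with a FIXED
# flip count, (A, B) solved exactly: used to check that polarity
# restoration never worsens the no-flip fit
vp_rss_fixed_flip <- function(ti, signals, k, t1_star) {
  y <- signals
  if (k > 0) y[seq_len(k)] <- -y[seq_len(k)]
  u <- exp(-ti / t1_star)
  fit <- stats::lm.fit(cbind(1, -u), y)
  sum(fit$residuals^2)
}

# ANCOVA oracle: dummy-variable multiple regression, partial r of x given
# patient intercepts
ancova_oracle <- function(data) {
  fit <- stats::lm(y ~ factor(patient) + x, data = data)
  sm <- summary(fit)$coefficients
  tv <- sm["x", "t value"]
  df <- fit$df.residual
  list(r = sign(tv) * sqrt(tv^2 / (tv^2 + df)),
       p = sm["x", "Pr(>|t|)"], df = df)
}

# independent circular-distance mirror (keeps invariant checks decoupled
# from the implementation under test)
circ_dist_pkg <- function(i, j, n) pmin(abs(i - j), n - abs(i - j))

# modular-arithmetic oracle for remote sector ids: the three most distal
# ring positions from the argmax, found by explicit distance ranking
remote_ids_oracle <- function(argmax, n) {
  d <- pmin(abs(seq_len(n) - argmax), n - abs(seq_len(n) - argmax))
  sort(order(-d, seq_len(n))[1:3])
}

# fast noise-free phantom parameters for geometry-heavy tests
quiet_phantom <- function(...) {
  phantom_params(noise_sd = 0, ...)
}

# elliptical star-shaped contour for non-circular geometry tests
ellipse_contour <- function(center, a, b, n = 64) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + a * cos(t), center[2] + b * sin(t))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
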