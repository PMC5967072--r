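# Pixelwise MOLLI T1 fitting.
#
# Model: y(TI) = A - B * exp(-TI / T1*), observed as magnitude data, so the
# earliest samples (pre-null) must be sign-restored before fitting.  The fit
# uses variable projection: for fixed T1* the model is linear in (A, B), so
# the nonlinear problem is a 1-D search over T1*.  Polarity restoration is an
# exhaustive search over the number k of earliest samples negated
# (k = 0 .. n-1); the (k, T1*) candidate with minimal residual RMS wins.
# Because candidate k = 0 is always tried, sign restoration can never
# increase the residual relative to the no-flip fit.
#
# The engine is vectorized over pixels: for each T1* grid value the linear
# (A, B) solve for every pixel and every flip count is obtained from running
# sums, and the winning candidate per pixel is then refined by a vectorized
# golden-section search on log(T1*).

.t1star_bounds <- function(ti) c(min(ti) / 20, max(ti) * 3)

# core: ti sorted ascending (length n_t), S n_t x n_px matrix of magnitude
# signals. Returns per-pixel parameter vectors.  Every flip candidate is
# refined independently (cheap: the refinement is vectorized over pixels),
# so the reported minimum is the true joint (k, T1*) minimizer.
.fit_t1_engine <- function(ti, S, n_grid = 64L, refine_iter = 48L) {
  n_t <- length(ti)
  n_px <- ncol(S)
  bounds <- .t1star_bounds(ti)
  grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = n_grid))

  Syy <- colSums(S * S)              # invariant under sign restoration
  csS <- apply(S, 2L, cumsum)        # csS[k, p] = sum of k earliest samples
  if (n_px == 1L) csS <- matrix(csS, ncol = 1L)
  Sy0 <- csS[n_t, ]

  # coarse grid: per flip candidate k, best grid index and RSS per pixel
  co_rss <- matrix(Inf, n_t, n_px)   # row k+1 = flip count k
  co_idx <- matrix(1L, n_t, n_px)
  lower_tri <- lower.tri(matrix(0, n_t, n_t), diag = TRUE) * 1

  for (i in seq_len(n_grid)) {
    u <- exp(-ti / grid[i])
    Su <- sum(u)
    Suu <- sum(u * u)
    denom <- n_t * Suu - Su * Su
    V <- u * S                       # row-recycled elementwise product
    csV <- lower_tri %*% V           # partial sums of u_j * S_jp
    Syu0 <- csV[n_t, ]
    for (k in 0:(n_t - 1L)) {
      Sy <- if (k == 0L) Sy0 else Sy0 - 2 * csS[k, ]
      Syu <- if (k == 0L) Syu0 else Syu0 - 2 * csV[k, ]
      slope <- (n_t * Syu - Su * Sy) / denom
      a <- (Sy - slope * Su) / n_t
      rss <- Syy - a * Sy - slope * Syu
      upd <- rss < co_rss[k + 1L, ]
      if (any(upd)) {
        co_rss[k + 1L, upd] <- rss[upd]
        co_idx[k + 1L, upd] <- i
      }
    }
  }

  gr <- (sqrt(5) - 1) / 2
  best <- list(rss = rep(Inf, n_px), t1_star = rep(NA_real_, n_px),
               a = rep(NA_real_, n_px), b = rep(NA_real_, n_px),
               k = rep(0L, n_px))

  for (k in 0:(n_t - 1L)) {
    Yf <- S
    if (k > 0L) Yf[seq_len(k), ] <- -Yf[seq_len(k), ]
    Sy <- colSums(Yf)
    rss_at <- function(t1s) {        # t1s: one candidate T1* per pixel
      U <- exp(outer(-ti, 1 / t1s))
      Su <- colSums(U)
      Suu <- colSums(U * U)
      Syu <- colSums(Yf * U)
      slope <- (n_t * Syu - Su * Sy) / (n_t * Suu - Su * Su)
      a <- (Sy - slope * Su) / n_t
      list(rss = Syy - a * Sy - slope * Syu, a = a, b = -slope)
    }
    idx <- co_idx[k + 1L, ]
    lo <- log(grid[pmax(idx - 1L, 1L)])
    hi <- log(grid[pmin(idx + 1L, n_grid)])
    for (it in seq_len(refine_iter)) {
      x1 <- hi - gr * (hi - lo)
      x2 <- lo + gr * (hi - lo)
      f1 <- rss_at(exp(x1))$rss
      f2 <- rss_at(exp(x2))$rss
      left <- f1 < f2
      hi[left] <- x2[left]
      lo[!left] <- x1[!left]
    }
    t1s <- exp((lo + hi) / 2)
    fin <- rss_at(t1s)
    upd <- is.finite(fin$rss) & fin$rss < best$rss
    if (any(upd)) {
      best$rss[upd] <- fin$rss[upd]
      best$t1_star[upd] <- t1s[upd]
      best$a[upd] <- fin$a[upd]
      best$b[upd] <- fin$b[upd]
      best$k[upd] <- k
    }
  }

  a <- best$a
  b <- best$b
  t1_star <- best$t1_star
  rss <- pmax(best$rss, 0)

  ratio <- b / a
  t1 <- t1_star * (ratio - 1)
  at_bound <- !is.na(t1_star) &
    (t1_star < bounds[1] * 1.001 | t1_star > bounds[2] * 0.999)
  ok <- is.finite(t1) & is.finite(a) & is.finite(b) & a > 0 & ratio > 1 & !at_bound
  reason <- rep(NA_character_, n_px)
  reason[!is.finite(t1) | !is.finite(a) | !is.finite(b)] <- "non-finite fit"
  bad_ratio <- is.finite(a) & is.finite(b) & (a <= 0 | ratio <= 1)
  reason[bad_ratio] <- "degenerate fit (B/A <= 1)"
  reason[at_bound] <- "T1* at search bound"

  list(t1 = t1, t1_star = t1_star, a = a, b = b,
       residual_rms = sqrt(rss / n_t), polarity_flips = best$k,
       ok = ok, reason = reason)
}

#' Fit T1 for a single pixel from MOLLI magnitude samples
#'
#' Three-parameter fit of `|A - B exp(-TI/T1*)|` with exhaustive polarity
#' restoration over the number of earliest samples negated, followed by the
#' Look-Locker correction `T1 = T1* (B/A - 1)`.  Never raises on finite
#' input: degenerate data (e.g. constant signals, apparent `B/A <= 1`) is
#' reported as `ok = FALSE` with a reason.
#'
#' @param times effective inversion times (ms), strictly positive, sorted
#'   ascending, at least 5 samples.
#' @param signals magnitude signals, same length as `times`.
#' @return An object of class `t1_fit`: a list with `t1`, `t1_star`, `a`,
#'   `b` (signal units), `residual_rms`, `polarity_flips`, `ok`, `reason`.
#' @export
fit_t1_pixel <- function(times, signals) {
  if (length(times) < 5L) user_stopf("need at least 5 samples, got %d", length(times))
  if (length(signals) != length(times))
    user_stopf("`times` and `signals` must have the same length")
  if (any(!is.finite(times)) || any(times <= 0))
    user_stopf("times must be finite and strictly positive")
  if (is.unsorted(times, strictly = TRUE))
    user_stopf("times must be sorted in strictly increasing order")
  if (any(!is.finite(signals))) {
    return(structure(list(t1 = NA_real_, t1_star = NA_real_, a = NA_real_,
                          b = NA_real_, residual_rms = NA_real_,
                          polarity_flips = NA_integer_, ok = FALSE,
                          reason = "non-finite signal"),
                     class = "t1_fit"))
  }
  r <- .fit_t1_engine(as.numeric(times), matrix(as.numeric(signals), ncol = 1L))
  structure(list(t1 = r$t1[1], t1_star = r$t1_star[1], a = r$a[1], b = r$b[1],
                 residual_rms = r$residual_rms[1],
                 polarity_flips = r$polarity_flips[1],
                 ok = r$ok[1], reason = r$reason[1]),
            class = "t1_fit")
}

#' @export
print.t1_fit <- function(x, ...) {
  if (x$ok)
    cat(sprintf("<t1_fit> T1 = %.2f ms (T1* = %.2f, B/A = %.3f, %d flips, rms %.3g)\n",
                x$t1, x$t1_star, x$b / x$a, x$polarity_flips, x$residual_rms))
  else
    cat(sprintf("<t1_fit> failed: %s\n", x$reason))
  invisible(x)
}

#' Fit a pixelwise T1 map from a MOLLI series
#'
#' Runs the [fit_t1_pixel()] model on every pixel inside `mask` (vectorized
#' over pixels).  Pixels whose fit fails (`ok = FALSE`, including pixels
#' with non-finite samples) are removed from the validity mask of the
#' returned map; their count is reported in a message and stored in the
#' `"n_excluded"` attribute.
#'
#' @param series a [molli_series()].
#' @param mask logical matrix selecting the pixels to fit.
#' @return A [scalar_map()] of T1 (ms) with attribute `n_excluded`.
#' @export
fit_t1_map <- function(series, mask) {
  if (!inherits(series, "molli_series")) user_stopf("`series` must be a molli_series")
  d <- dim(series$data)
  if (!is.logical(mask) || !identical(dim(mask), d[1:2]))
    user_stopf("`mask` must be a logical matrix matching the series grid")
  idx <- which(mask)
  if (!length(idx)) user_stopf("empty mask: no pixels to fit")

  ord <- order(series$ti)
  ti <- series$ti[ord]
  n_t <- length(ti)
  S <- vapply(ord, function(t) series$data[, , t][idx], numeric(length(idx)))
  S <- t(S)                                 # n_t x n_px

  finite <- colSums(is.finite(S)) == n_t
  t1 <- rep(NA_real_, length(idx))
  ok <- rep(FALSE, length(idx))
  if (any(finite)) {
    r <- .fit_t1_engine(ti, S[, finite, drop = FALSE])
    t1[finite] <- r$t1
    ok[finite] <- r$ok
  }

  out <- matrix(NA_real_, d[1], d[2])
  out[idx] <- ifelse(ok, t1, NA_real_)
  new_mask <- matrix(FALSE, d[1], d[2])
  new_mask[idx[ok]] <- TRUE
  n_excluded <- sum(!ok)
  if (n_excluded > 0)
    message(sprintf("fit_t1_map: %d of %d pixels excluded (failed fits)",
                    n_excluded, length(idx)))
  m <- scalar_map(out, new_mask, quantity = "t1", units = "ms")
  attr(m, "n_excluded") <- n_excluded
  m
}
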