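#' MOLLI acquisition scheme
#'
#' Describes a Modified Look-Locker Inversion recovery (MOLLI) sampling
#' scheme in the usual "groups(pauses)" notation.  The default 3(3)3(3)6
#' scheme acquires three looks of 3, 3 and 6 images, separated by 3-beat
#' recovery pauses, for 11 images in total.  Each look g starts with its own
#' base inversion delay and samples subsequent heartbeats, so the effective
#' inversion time of image k (0-based) within look g is
#' `base_ti[g] + k * RR` with `RR = 60000 / heart_rate` ms.
#'
#' The base inversion delays of the prototype sequence are not standardized;
#' the defaults (120, 200, 280 ms) are typical minimum-TI increments and can
#' be changed freely.
#'
#' @param groups integer vector: images per look.
#' @param pauses integer vector (length `length(groups) - 1`): recovery beats
#'   between looks.  Recorded for provenance; the effective TIs depend only
#'   on `groups` and `base_ti`.
#' @param base_ti numeric vector, same length as `groups`: base inversion
#'   delay of each look (ms).
#' @return An object of class `molli_scheme`.
#' @export
molli_scheme <- function(groups = c(3L, 3L, 6L), pauses = c(3L, 3L),
                         base_ti = c(120, 200, 280)) {
  if (length(base_ti) != length(groups))
    user_stopf("`base_ti` must have one entry per look")
  if (length(pauses) != length(groups) - 1L)
    user_stopf("`pauses` must have length(groups) - 1 entries")
  if (any(groups < 1) || any(base_ti <= 0))
    user_stopf("groups must be >= 1 and base inversion delays positive")
  structure(list(groups = as.integer(groups), pauses = as.integer(pauses),
                 base_ti = as.numeric(base_ti)),
            class = "molli_scheme")
}

#' @export
print.molli_scheme <- function(x, ...) {
  cat(sprintf("<molli_scheme> %s, base TI %s ms\n",
              paste0(x$groups, "(", c(x$pauses, ""), ")", collapse = ""),
              paste(x$base_ti, collapse = "/")))
  invisible(x)
}

#' Effective inversion times of a MOLLI scheme
#'
#' @param scheme a [molli_scheme()].
#' @param heart_rate heart rate in bpm (one RR interval = 60000/heart_rate ms).
#' @return Numeric vector of effective inversion times (ms) in acquisition
#'   order (look by look).
#' @export
molli_ti <- function(scheme = molli_scheme(), heart_rate = 60) {
  chk_num(heart_rate, "heart_rate", lo = 20, hi = 250)
  rr <- 60000 / heart_rate
  unlist(lapply(seq_along(scheme$groups), function(g)
    scheme$base_ti[g] + (seq_len(scheme$groups[g]) - 1) * rr))
}

#' Magnitude inversion-recovery signal model
#'
#' The three-parameter Look-Locker model of the apparent recovery,
#' `S(TI) = | A - B * exp(-TI / T1*) |`, with the apparent relaxation time
#' tied to the true T1 by the Look-Locker correction
#' `T1* = T1 / (B/A - 1)`.  With a perfect inversion (`B = 2A`) the apparent
#' and true T1 coincide and the signal null lies at `TI = T1 * ln 2`.
#'
#' @param ti inversion times (ms); vector, matrix or array.
#' @param t1 true T1 (ms); scalar or conformable with `ti`.
#' @param a,b model amplitudes (signal units), `b/a > 1`.
#' @return Magnitude signal, same shape as the broadcast of `ti` and `t1`.
#' @export
molli_signal <- function(ti, t1, a = 100, b = 200) {
  if (any(t1 <= 0, na.rm = TRUE)) user_stopf("t1 must be strictly positive")
  if (any(b / a <= 1)) user_stopf("model requires b/a > 1")
  t1_star <- t1 / (b / a - 1)
  abs(a - b * exp(-ti / t1_star))
}

#' Simulate a MOLLI magnitude sample series for one T1 value
#'
#' Generates the 11 samples (for the default 3(3)3(3)6 scheme) a MOLLI
#' acquisition would measure for a pixel of true T1 `t1`, with Gaussian
#' noise of standard deviation `noise_sd` added to the magnitude signal.
#'
#' @param t1 true T1 (ms), strictly positive.
#' @param scheme a [molli_scheme()].
#' @param heart_rate bpm.
#' @param noise_sd Gaussian noise SD in signal units (`a = 100` scale).
#' @param a,b model amplitudes.
#' @return A data frame with columns `ti` (ms, acquisition order) and
#'   `signal`.
#' @export
simulate_molli_signal <- function(t1, scheme = molli_scheme(), heart_rate = 60,
                                  noise_sd = 0, a = 100, b = 200) {
  chk_num(t1, "t1", lo = 0, open = TRUE, hi = Inf)
  chk_num(noise_sd, "noise_sd", lo = 0)
  ti <- molli_ti(scheme, heart_rate)
  s <- molli_signal(ti, t1, a = a, b = b)
  if (noise_sd > 0) s <- s + stats::rnorm(length(s), 0, noise_sd)
  data.frame(ti = ti, signal = s)
}
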