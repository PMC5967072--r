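# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = character()) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "cmrpet_error", "error")))
}

# validation failures are "user" errors (CLI exit code 1, not 2)
user_stopf <- function(fmt, ...) stopf(fmt, ..., class = "cmrpet_user_error")

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

chk_num <- function(x, name, lo = -Inf, hi = Inf, open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    user_stopf("`%s` must be a single finite number", name)
  bad <- if (open) (x <= lo || x >= hi) else (x < lo || x > hi)
  if (bad)
    user_stopf("`%s` = %g is outside %s%g, %g%s", name, x,
               if (open) "(" else "[", lo, hi, if (open) ")" else "]")
  x
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so that no hidden global state leaks between calls.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# circular distance between 1-based sector ids on a ring of n sectors
circ_dist <- function(i, j, n) {
  d <- abs(i - j)
  pmin(d, n - d)
}

# wrap angles to (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}
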