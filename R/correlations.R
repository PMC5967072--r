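# Statistical layer: between-subject correlation of per-subject means,
# within-subject (repeated-measures ANCOVA) correlation, per-subject
# regression slopes, and image-maximum vs marker / infarct-size correlations.
# R and p are Pearson throughout, two-sided, no multiple-testing correction
# by default (5% significance convention); a Bonferroni switch is provided
# for users who want it.

corr_result <- function(r, df, n, kind) {
  r <- max(-1, min(1, r))
  t <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), df)
  data.frame(kind = kind, r = r, p = max(p, .Machine$double.xmin),
             df = df, n = n)
}

check_paired <- function(data) {
  need <- c("patient", "x", "y")
  if (!all(need %in% names(data)))
    user_stopf("paired data must have columns patient, x, y")
  data <- data[stats::complete.cases(data[, need]), need]
  data
}

#' Between-subject correlation of per-subject means
#'
#' Pearson correlation over one point per patient (the patient's mean of x
#' against its mean of y); p from the t distribution with k - 2 degrees of
#' freedom, k = number of patients.
#'
#' @param data data frame with columns `patient`, `x`, `y` (paired,
#'   non-excluded sector values).
#' @return One-row data frame: `kind`, `r`, `p`, `df`, `n`.
#' @export
between_subject_corr <- function(data) {
  data <- check_paired(data)
  mx <- tapply(data$x, data$patient, mean)
  my <- tapply(data$y, data$patient, mean)
  k <- length(mx)
  if (k < 3) user_stopf("between-subject correlation needs >= 3 patients, got %d", k)
  if (stats::sd(mx) == 0 || stats::sd(my) == 0)
    user_stopf("zero variance in per-patient means")
  corr_result(stats::cor(mx, my), df = k - 2, n = k, kind = "between")
}

#' Within-subject (repeated-measures ANCOVA) correlation
#'
#' Pooled Pearson correlation of patient-mean-centered pairs
#' `(x_ij - xbar_i, y_ij - ybar_i)` with `df = N - k - 1` (N sectors
#' total, k patients) — algebraically the partial correlation of y with x
#' adjusted for patient in the dummy-variable multiple regression
#' (analysis of covariance), i.e. the repeated-measures correlation.
#' It isolates intra-slice co-localization from between-patient level
#' differences.
#'
#' Patients with fewer than 2 sectors or zero within-patient x variance are
#' dropped with a warning; if all are dropped, an error is raised.
#'
#' @param data data frame with columns `patient`, `x`, `y`.
#' @return One-row data frame: `kind`, `r`, `p`, `df`, `n`.
#' @export
within_subject_corr <- function(data) {
  data <- check_paired(data)
  grp <- split(data, data$patient)
  usable <- vapply(grp, function(d)
    nrow(d) >= 2 && stats::sd(d$x) > 0, logical(1))
  if (any(!usable))
    warnf("dropping %d patient(s) with < 2 sectors or zero within-patient x variance",
          sum(!usable))
  grp <- grp[usable]
  if (length(grp) < 2)
    user_stopf("within-subject correlation needs >= 2 usable patients")
  xc <- unlist(lapply(grp, function(d) d$x - mean(d$x)), use.names = FALSE)
  yc <- unlist(lapply(grp, function(d) d$y - mean(d$y)), use.names = FALSE)
  n_tot <- length(xc)
  k <- length(grp)
  df <- n_tot - k - 1
  if (df < 1) user_stopf("not enough sectors for within-subject correlation (df = %d)", df)
  if (sum(yc^2) == 0) user_stopf("zero within-patient variance in y")
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  corr_result(r, df = df, n = n_tot, kind = "within")
}

#' Per-subject ordinary least-squares slopes
#'
#' One linear regression of y on x per patient (the individual regression
#' lines whose heterogeneity distinguishes co-localization from shared
#' absolute scale).  Patients with fewer than 3 sectors or degenerate x
#' variance are flagged and carry `NA` coefficients.
#'
#' @param data data frame with columns `patient`, `x`, `y`.
#' @return Data frame per patient: `patient`, `n`, `slope`, `intercept`,
#'   `r`, `flagged`.
#' @export
per_subject_slopes <- function(data) {
  data <- check_paired(data)
  out <- do.call(rbind, lapply(split(data, data$patient), function(d) {
    flag <- nrow(d) < 3 || stats::sd(d$x) == 0
    if (flag) {
      data.frame(patient = d$patient[1], n = nrow(d), slope = NA_real_,
                 intercept = NA_real_, r = NA_real_, flagged = TRUE)
    } else {
      slope <- stats::cov(d$x, d$y) / stats::var(d$x)
      data.frame(patient = d$patient[1], n = nrow(d), slope = slope,
                 intercept = mean(d$y) - slope * mean(d$x),
                 r = if (stats::sd(d$y) > 0) stats::cor(d$x, d$y) else NA_real_,
                 flagged = FALSE)
    }
  }))
  rownames(out) <- NULL
  out
}

#' Image-maximum (or remote) vs marker / infarct-size correlations
#'
#' Simple Pearson r and p for every pair of one column of `image` and one
#' column of `markers`, with pairwise deletion of missing values (the
#' per-cell n is reported).  Cells with fewer than 3 complete pairs are
#' `NA`.
#'
#' @param image data frame: `patient` plus numeric image summary columns
#'   (e.g. `max_ecv`, `max_native_t1`, `max_fdg_suv`, `max_fdg_tbr`,
#'   remotes).
#' @param markers data frame: `patient` plus numeric marker columns
#'   (blood-marker peaks, infarct size).
#' @param bonferroni apply a Bonferroni correction over all computed cells
#'   (off by default, matching the plain 5%-level convention).
#' @return Tidy data frame: `image`, `marker`, `n`, `r`, `p`.
#' @export
marker_correlations <- function(image, markers, bonferroni = FALSE) {
  for (d in list(image, markers))
    if (!"patient" %in% names(d)) user_stopf("both tables need a `patient` column")
  merged <- merge(image, markers, by = "patient")
  ivars <- setdiff(names(image), "patient")
  mvars <- setdiff(names(markers), "patient")
  out <- do.call(rbind, lapply(ivars, function(iv) {
    do.call(rbind, lapply(mvars, function(mv) {
      ok <- is.finite(merged[[iv]]) & is.finite(merged[[mv]])
      n <- sum(ok)
      if (n < 3)
        return(data.frame(image = iv, marker = mv, n = n,
                          r = NA_real_, p = NA_real_))
      ct <- stats::cor.test(merged[[iv]][ok], merged[[mv]][ok])
      data.frame(image = iv, marker = mv, n = n,
                 r = unname(ct$estimate), p = ct$p.value)
    }))
  }))
  if (bonferroni) {
    m <- sum(!is.na(out$p))
    out$p <- pmin(1, out$p * m)
  }
  rownames(out) <- NULL
  out
}
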