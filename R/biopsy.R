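# "Imaging biopsy" statistics: per-patient maximum (mean of the two highest
# sector values), remote reference (three sectors as distal as possible from
# the highest sector on the ring), and cross-modality argmax distances.

#' Maximum "imaging biopsy" value of a sector profile
#'
#' Mean of the two largest non-excluded sector values; ties broken toward
#' the lower sector id, so the result is deterministic.
#'
#' @param values numeric vector of per-sector values (index = sector id).
#' @param excluded logical vector flagging excluded sectors (default none);
#'   `NA` values are treated as excluded.
#' @return List with `value` (mean of the two highest), `sectors` (their
#'   ids, ascending) and `argmax` (id of the single highest sector).
#' @export
max_biopsy <- function(values, excluded = rep(FALSE, length(values))) {
  stopifnot(length(excluded) == length(values))
  ok <- !excluded & !is.na(values)
  if (sum(ok) < 2)
    user_stopf("need at least 2 non-excluded sectors, got %d", sum(ok))
  ids <- which(ok)
  ord <- ids[order(-values[ids], ids)]
  top <- ord[1:2]
  list(value = mean(values[top]), sectors = sort(top), argmax = ord[1])
}

#' Remote sector selection on the ring
#'
#' Codifies "as distal as possible": the sector diametrically opposite the
#' single highest sector, `((argmax - 1 + n/2) mod n) + 1`, and its two ring
#' neighbors.  If any of the three is excluded it is replaced by the
#' next-most-distal valid sector (ties toward the lower id), keeping the set
#' size at three.
#'
#' @param values per-sector values (used only to locate the argmax when not
#'   supplied).
#' @param excluded logical exclusion flags.
#' @param argmax id of the highest sector; computed via [max_biopsy()] when
#'   `NULL`.
#' @param n_sectors ring size (defaults to `length(values)`).
#' @return List with `sectors` (three ids, ascending), `value` (their mean)
#'   and `argmax`.
#' @export
remote_selection <- function(values, excluded = rep(FALSE, length(values)),
                             argmax = NULL, n_sectors = length(values)) {
  n <- n_sectors
  ok <- !excluded & !is.na(values)
  if (is.null(argmax)) argmax <- max_biopsy(values, excluded)$argmax
  opposite <- (argmax - 1L + n %/% 2L) %% n + 1L
  ideal <- (opposite - 1L + c(-1L, 0L, 1L)) %% n + 1L
  chosen <- ideal[ok[ideal]]
  if (length(chosen) < 3L) {
    pool <- setdiff(which(ok), c(chosen, argmax))
    pool <- pool[order(-circ_dist(pool, argmax, n), pool)]
    chosen <- c(chosen, utils::head(pool, 3L - length(chosen)))
  }
  if (length(chosen) < 3L)
    user_stopf("cannot find 3 valid remote sectors distal to sector %d", argmax)
  chosen <- sort(as.integer(chosen))
  list(sectors = chosen, value = mean(values[chosen]), argmax = argmax)
}

#' Circular distance between two sector ids
#'
#' @param i,j 1-based sector ids.
#' @param n_sectors ring size.
#' @return `min(|i - j|, n - |i - j|)` in sectors.
#' @export
argmax_distance <- function(i, j, n_sectors) {
  circ_dist(as.integer(i), as.integer(j), as.integer(n_sectors))
}

#' Per-patient biopsy summary from a tidy sector table
#'
#' Maximum and remote statistics are located independently for each imaging
#' signal (never anchored to a reference modality, which would bias the
#' cross-modality comparison).
#'
#' @param sectors tidy sector table from [sector_table()] (possibly several
#'   patients row-bound).
#' @return Data frame with one row per patient x modality: `max_value`,
#'   `max_sector_1/2`, `argmax`, `remote_value`, `remote_1/2/3`,
#'   `n_sectors`, `n_excluded`.
#' @export
biopsy_summary <- function(sectors) {
  need <- c("patient", "sector", "modality", "value", "excluded", "n_sectors")
  if (!all(need %in% names(sectors)))
    user_stopf("sector table must have columns %s", paste(need, collapse = ", "))
  parts <- split(sectors, list(sectors$patient, sectors$modality), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d) {
    d <- d[order(d$sector), ]
    mx <- max_biopsy(d$value, d$excluded)
    rm_ <- remote_selection(d$value, d$excluded, argmax = mx$argmax,
                            n_sectors = d$n_sectors[1])
    data.frame(patient = d$patient[1], modality = d$modality[1],
               n_sectors = d$n_sectors[1], n_excluded = sum(d$excluded),
               max_value = mx$value, max_sector_1 = mx$sectors[1],
               max_sector_2 = mx$sectors[2], argmax = mx$argmax,
               remote_value = rm_$value, remote_1 = rm_$sectors[1],
               remote_2 = rm_$sectors[2], remote_3 = rm_$sectors[3])
  }))
  out <- out[order(out$patient, out$modality), ]
  rownames(out) <- NULL
  out
}

#' Cross-modality argmax distances per patient
#'
#' @param summary output of [biopsy_summary()].
#' @return Data frame `patient`, `pair`, `distance` (sectors) for every
#'   unordered modality pair.
#' @export
argmax_distances <- function(summary) {
  out <- do.call(rbind, lapply(split(summary, summary$patient), function(d) {
    if (nrow(d) < 2) return(NULL)
    cmb <- utils::combn(seq_len(nrow(d)), 2)
    data.frame(patient = d$patient[1],
               pair = apply(cmb, 2, function(ij)
                 paste(sort(d$modality[ij]), collapse = "/")),
               distance = apply(cmb, 2, function(ij)
                 argmax_distance(d$argmax[ij[1]], d$argmax[ij[2]],
                                 d$n_sectors[1])))
  }))
  rownames(out) <- NULL
  out
}
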