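# Validation layer: pairing of estimated and measured per-cycle peak
# collision pressures and the summary statistics used to compare them.

#' Pair estimated and measured per-cycle peaks by time
#'
#' Greedy nearest-time matching with a tolerance of half the median
#' measured period; unmatched cycles on either side are dropped and
#' counted.
#'
#' @param est,meas [peak_collision_per_cycle()] results (`cycle_peaks`),
#'   or lists with `cycle_times` and `peaks`.
#' @return an object of class `paired_peaks`: data frame `cycle_times`,
#'   `measured`, `estimated`, `dt`, with attributes `dropped_est` and
#'   `dropped_meas`.
#' @export
match_cycles <- function(est, meas) {
  te <- est$cycle_times; pe <- est$peaks
  tm <- meas$cycle_times; pm <- meas$peaks
  stopifnot(length(te) == length(pe), length(tm) == length(pm),
            length(te) > 0, length(tm) > 0)
  if (max(te) < min(tm) || max(tm) < min(te))
    stop("series do not overlap in time", call. = FALSE)
  tol <- 0.5 * median(diff(tm))
  if (!is.finite(tol)) tol <- Inf
  cand <- expand.grid(i = seq_along(te), j = seq_along(tm))
  cand$dt <- abs(te[cand$i] - tm[cand$j])
  cand <- cand[cand$dt < tol, , drop = FALSE]
  cand <- cand[order(cand$dt), , drop = FALSE]
  used_i <- logical(length(te)); used_j <- logical(length(tm))
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_i[i] && !used_j[j]) {
      used_i[i] <- TRUE; used_j[j] <- TRUE
      rows[[length(rows) + 1]] <- data.frame(cycle_times = tm[j],
                                             measured = pm[j],
                                             estimated = pe[i],
                                             dt = te[i] - tm[j])
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cycle_times), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("paired_peaks", "data.frame"),
            dropped_est = sum(!used_i), dropped_meas = sum(!used_j))
}

#' Agreement statistics between estimated and measured peaks
#'
#' @param pairs a [match_cycles()] result (or data frame with `measured`
#'   and `estimated`).
#' @return list with `rmse`, `mae` (same units as the inputs), `mape`
#'   (percent, measured in the denominator), and `n`.
#' @export
error_stats <- function(pairs) {
  m <- pairs$measured; e <- pairs$estimated
  stopifnot(length(m) == length(e), length(m) >= 1)
  if (any(m == 0))
    stop("mape undefined: measured peaks contain zero", call. = FALSE)
  err <- e - m
  list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
       mape = 100 * mean(abs(err) / abs(m)), n = length(m))
}

#' Peak collision to subglottal pressure ratio
#'
#' @param peaks a `cycle_peaks` object (or list with `peaks`).
#' @param mean_psub mean subglottal pressure (cm H2O), `> 0`.
#' @return `mean(peaks) / mean_psub`.
#' @export
collision_subglottal_ratio <- function(peaks, mean_psub) {
  stopifnot(mean_psub > 0)
  mean(peaks$peaks) / mean_psub
}
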