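# Production-rate estimation: the measured half of an MMP. Concentration
# trajectories are linear over the 0-4 h assay window, so the rate is the
# two-point slope between 2 h and 4 h on replicate-averaged values, with the
# matched no-spike-in control rate subtracted.

#' Average biological replicates per timepoint
#'
#' Arithmetic mean of `conc_mM` within each
#' (donor, condition, scfa, timepoint) group; the replicate index is cleared
#' (set to 1). If a group has an uneven number of wells across timepoints
#' (a missing well), the mean is taken over the available wells and a
#' warning is issued.
#'
#' @param x Long SCFA data frame (see [read_scfa_table()]).
#' @return Long SCFA data frame with one row per group.
#' @export
average_replicates <- function(x) {
  if (is.null(x) || nrow(x) == 0L) stop("empty replicate group")
  ag <- aggregate(conc_mM ~ donor + condition + scfa + timepoint_h,
                  data = x, FUN = mean)
  n <- aggregate(conc_mM ~ donor + condition + scfa + timepoint_h,
                 data = x, FUN = length)
  series <- paste(n$donor, n$condition, n$scfa)
  uneven <- tapply(n$conc_mM, series, function(k) length(unique(k)) > 1L)
  if (any(uneven))
    warning(sprintf("uneven replicate counts across timepoints for: %s",
                    paste(names(uneven)[uneven], collapse = "; ")))
  ag$replicate <- 1L
  ag[order(ag$donor, ag$condition, ag$scfa, ag$timepoint_h),
     c("donor", "condition", "timepoint_h", "replicate", "scfa", "conc_mM")]
}

#' Replicate agreement QC
#'
#' For every (donor, condition, timepoint, SCFA) group with at least two
#' replicates, computes the coefficient of variation
#' `100 * sd / mean` (sample sd, n-1 denominator) and, for pairs, the
#' percentage difference `100 * |a - b| / mean`. The overall statistic is
#' the unweighted mean of per-group CVs. Groups with zero mean are flagged
#' (`zero_mean`) and excluded from the overall mean rather than silently
#' dropped.
#'
#' @param x Long SCFA data frame with replicates.
#' @return Object of class `"replicate_qc"`: list with `pairs` (per-group
#'   data frame), `overall_cv`, `overall_pct_diff`, `n_pairs`, `n_flagged`.
#' @export
replicate_cv <- function(x) {
  grp <- interaction(x$donor, x$condition, x$timepoint_h, x$scfa, drop = TRUE)
  keep <- names(which(table(grp) >= 2L))
  if (!length(keep)) stop("need at least one group with >= 2 replicates")
  rows <- lapply(keep, function(g) {
    sub <- x[grp == g, ]
    v <- sub$conc_mM
    m <- mean(v)
    data.frame(donor = sub$donor[1L], condition = sub$condition[1L],
               timepoint_h = sub$timepoint_h[1L], scfa = sub$scfa[1L],
               n = length(v), mean = m,
               cv = if (m > 0) 100 * sd(v) / m else NA_real_,
               pct_diff = if (length(v) == 2L && m > 0)
                 100 * abs(diff(v)) / m else NA_real_,
               zero_mean = m == 0,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  structure(list(pairs = pairs,
                 overall_cv = mean(pairs$cv[!pairs$zero_mean], na.rm = TRUE),
                 overall_pct_diff = mean(pairs$pct_diff[!pairs$zero_mean],
                                         na.rm = TRUE),
                 n_pairs = nrow(pairs),
                 n_flagged = sum(pairs$zero_mean)),
            class = "replicate_qc")
}

#' @export
print.replicate_qc <- function(x, ...) {
  cat(sprintf(
    "Replicate QC: %d groups; overall CV %.1f%%; overall %%diff %.1f%%; %d zero-mean flagged\n",
    x$n_pairs, x$overall_cv, x$overall_pct_diff, x$n_flagged))
  invisible(x)
}

#' Two-point production rate
#'
#' Slope `(C(t_end) - C(t_start)) / (t_end - t_start)` of a concentration
#' series, in mM/h.
#'
#' @param timepoint_h Numeric vector of timepoints (hours).
#' @param conc_mM Concentrations (mM) at those timepoints.
#' @param t_start,t_end Rate window endpoints in hours (defaults 2 and 4).
#' @return Rate in mM/h.
#' @export
production_rate <- function(timepoint_h, conc_mM, t_start = 2, t_end = 4) {
  stopifnot(t_end > t_start, length(timepoint_h) == length(conc_mM))
  i0 <- match(t_start, timepoint_h)
  i1 <- match(t_end, timepoint_h)
  if (is.na(i0)) stop(sprintf("missing timepoint %g h", t_start))
  if (is.na(i1)) stop(sprintf("missing timepoint %g h", t_end))
  (conc_mM[i1] - conc_mM[i0]) / (t_end - t_start)
}

#' Production rates for a whole cohort table
#'
#' Replicates are averaged first (the two alternatives coincide for the
#' two-point slope when replication is balanced), then one rate per
#' (donor, condition, SCFA) is computed. `method = "least_squares"` instead
#' fits an ordinary regression over all timepoints inside the window
#' (inclusive), for sensitivity analysis.
#'
#' @param x Long SCFA data frame.
#' @param t_start,t_end Window endpoints (hours).
#' @param method `"two_point"` (default) or `"least_squares"`.
#' @return Data frame `donor`, `condition`, `scfa`, `rate_mM_per_h` with the
#'   window stored in attribute `"window"`.
#' @export
production_rates <- function(x, t_start = 2, t_end = 4,
                             method = c("two_point", "least_squares")) {
  method <- match.arg(method)
  avg <- suppressWarnings(average_replicates(x))
  grp <- unique(avg[, c("donor", "condition", "scfa")])
  grp$rate_mM_per_h <- vapply(seq_len(nrow(grp)), function(i) {
    sub <- avg[avg$donor == grp$donor[i] & avg$condition == grp$condition[i] &
                 avg$scfa == grp$scfa[i], ]
    if (method == "two_point") {
      tryCatch(production_rate(sub$timepoint_h, sub$conc_mM, t_start, t_end),
               error = function(e)
                 stop(sprintf("%s (donor %s, %s, %s)", conditionMessage(e),
                              grp$donor[i], grp$condition[i], grp$scfa[i])))
    } else {
      w <- sub$timepoint_h >= t_start & sub$timepoint_h <= t_end
      if (sum(w) < 2L)
        stop(sprintf("fewer than 2 timepoints in window for donor %s, %s, %s",
                     grp$donor[i], grp$condition[i], grp$scfa[i]))
      unname(coef(lm(conc_mM ~ timepoint_h, data = sub[w, ]))[2L])
    }
  }, 0)
  rownames(grp) <- NULL
  structure(grp, window = c(t_start, t_end))
}

#' Control-subtract a single fiber rate
#'
#' @param fiber_rate,control_rate One-row data frames (or named lists) with
#'   fields `donor`, `scfa` and `rate_mM_per_h`; `fiber_rate` additionally
#'   names its `condition`. Donor and SCFA must match.
#' @return One-row data frame `donor`, `fiber`, `scfa`, `rate_mM_per_h`;
#'   the net rate may be negative.
#' @export
net_production_rate <- function(fiber_rate, control_rate) {
  if (!identical(fiber_rate$donor, control_rate$donor))
    stop("donor mismatch between fiber and control rates")
  if (!identical(fiber_rate$scfa, control_rate$scfa))
    stop("SCFA mismatch between fiber and control rates")
  data.frame(donor = fiber_rate$donor, fiber = fiber_rate$condition,
             scfa = fiber_rate$scfa,
             rate_mM_per_h = fiber_rate$rate_mM_per_h -
               control_rate$rate_mM_per_h,
             stringsAsFactors = FALSE)
}

#' Control-subtract all fiber rates in a cohort
#'
#' Subtracts each donor's control (no spike-in) rate from the matched fiber
#' rate for the same SCFA. Net rates may be negative and are retained as-is.
#'
#' @param rates Output of [production_rates()], containing a `"control"`
#'   condition for every donor and SCFA.
#' @return Data frame `donor`, `fiber`, `scfa`, `rate_mM_per_h`.
#' @export
net_production_rates <- function(rates) {
  ctrl <- rates[rates$condition == "control", ]
  fib <- rates[rates$condition != "control", ]
  if (!nrow(ctrl)) stop("no control-condition rates present")
  idx <- match(paste(fib$donor, fib$scfa), paste(ctrl$donor, ctrl$scfa))
  if (anyNA(idx))
    stop(sprintf("missing control rate for donor %s (%s)",
                 fib$donor[which(is.na(idx))[1L]],
                 fib$scfa[which(is.na(idx))[1L]]))
  out <- data.frame(donor = fib$donor, fiber = fib$condition, scfa = fib$scfa,
                    rate_mM_per_h = fib$rate_mM_per_h -
                      ctrl$rate_mM_per_h[idx],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
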