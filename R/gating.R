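REJECTED <- NA_integer_

#' Detect respiratory cycles in an amplitude trace
#'
#' Cycles are delimited at successive end-expiratory minima of a lightly
#' smoothed copy of the signal. Each cycle is flagged valid or invalid by a
#' configurable rule; the default declares a cycle valid when its period lies
#' within `period_factor` times the median period and its peak-to-trough range
#' is at least `range_factor` times the median range. (The RPM device's own
#' valid-cycle rule is proprietary; this one is a declared stand-in.)
#'
#' @param trace a `resp_trace`.
#' @param validity_rule list with `period_factor` (length-2) and
#'   `range_factor` (scalar).
#' @param smooth_s Gaussian pre-smoothing of the signal for extrema detection,
#'   in seconds.
#' @return a `cycle_set`: data.frame with one row per cycle (`start_s`,
#'   `end_s`, `period_s`, `amp_max`, `amp_min`, `valid`) and an attribute
#'   `sample_cycle` mapping every trace sample to its cycle (NA outside).
#' @export
detect_cycles <- function(trace,
                          validity_rule = list(period_factor = c(0.5, 2),
                                               range_factor = 0.3),
                          smooth_s = 0.15) {
  stopifnot(inherits(trace, "resp_trace"))
  t <- trace$time_s; a <- trace$amplitude
  dt <- stats::median(diff(t))
  sm <- a
  if (smooth_s > 0) {
    k <- gauss_kernel(smooth_s / dt)
    sm <- as.numeric(conv_dim(array(a, c(length(a), 1, 1)), k, 1L))
    # zero padding biases the ends; renormalise by the kernel mass actually used
    ones <- as.numeric(conv_dim(array(1, c(length(a), 1, 1)), k, 1L))
    sm <- sm / ones
  }
  d <- diff(sm)
  n <- length(d)
  if (n < 2L) stop("trace too short for cycle detection")
  minima <- which(d[-n] <= 0 & d[-1] > 0) + 1L
  if (length(minima) < 2L) {
    stop("fewer than 2 respiratory minima detected; cannot delimit cycles")
  }
  nc <- length(minima) - 1L
  start_i <- minima[-length(minima)]
  end_i <- minima[-1]
  amp_max <- amp_min <- numeric(nc)
  for (j in seq_len(nc)) {
    seg <- a[start_i[j]:end_i[j]]
    amp_max[j] <- max(seg)
    amp_min[j] <- min(seg)
  }
  period <- t[end_i] - t[start_i]
  rng <- amp_max - amp_min
  med_p <- stats::median(period)
  med_r <- stats::median(rng)
  valid <- period >= validity_rule$period_factor[1] * med_p &
    period <= validity_rule$period_factor[2] * med_p &
    rng >= validity_rule$range_factor * med_r
  sample_cycle <- rep(NA_integer_, length(t))
  for (j in seq_len(nc)) {
    hi <- if (j == nc) end_i[j] else end_i[j] - 1L
    sample_cycle[start_i[j]:hi] <- j
  }
  cs <- data.frame(start_s = t[start_i], end_s = t[end_i], period_s = period,
                   amp_max = amp_max, amp_min = amp_min, valid = valid)
  attr(cs, "sample_cycle") <- sample_cycle
  class(cs) <- c("cycle_set", class(cs))
  cs
}

#' Amplitude gating thresholds
#'
#' The upper threshold is the mean plus one standard deviation (sample
#' convention) of the valid-cycle amplitude maxima; the lower threshold is the
#' mean of the valid-cycle minima. Five equidistant bins span the interval.
#'
#' @param cycles a `cycle_set`.
#' @param n_bins number of respiratory amplitude bins.
#' @return `gating_thresholds`: list with `a_max`, `a_min`, `edges`.
#' @export
compute_thresholds <- function(cycles, n_bins = 5L) {
  stopifnot(inherits(cycles, "cycle_set"))
  v <- cycles[cycles$valid, , drop = FALSE]
  if (nrow(v) < 2L) stop("need at least 2 valid cycles to form thresholds")
  a_max <- mean(v$amp_max) + stats::sd(v$amp_max)
  a_min <- mean(v$amp_min)
  if (!(a_max > a_min)) stop("degenerate trace: upper threshold <= lower threshold")
  structure(list(a_max = a_max, a_min = a_min,
                 edges = seq(a_min, a_max, length.out = n_bins + 1L)),
            class = "gating_thresholds")
}

#' Assign respiratory amplitude bins
#'
#' Bin 1 is the most-inspired (top) amplitude interval, bin 5 (default) the
#' end-expiratory (bottom) interval. Samples below the lower threshold are
#' clipped into the bottom bin; samples above the upper threshold and samples
#' in invalid cycles (or outside any cycle) are rejected (`NA`).
#'
#' @param trace `resp_trace`; `cycles` as from [detect_cycles()];
#'   `thresholds` as from [compute_thresholds()].
#' @param n_bins number of bins (must match the thresholds).
#' @return integer vector of labels per trace sample, `NA` = rejected; carries
#'   attribute `invalid_cycle` (logical per sample).
#' @export
assign_respiratory_bins <- function(trace, cycles, thresholds, n_bins = 5L) {
  stopifnot(inherits(thresholds, "gating_thresholds"),
            length(thresholds$edges) == n_bins + 1L)
  a <- trace$amplitude
  sc <- attr(cycles, "sample_cycle")
  stopifnot(length(sc) == length(a))
  in_valid <- !is.na(sc) & cycles$valid[ifelse(is.na(sc), 1L, sc)]
  lab <- rep(NA_integer_, length(a))
  ac <- pmax(a, thresholds$a_min)                      # clip below a_min into bottom bin
  k <- findInterval(ac, thresholds$edges, rightmost.closed = TRUE)
  r <- n_bins + 1L - k                                 # interval 1 (lowest) -> bin n_bins
  ok <- in_valid & a <= thresholds$a_max
  lab[ok] <- r[ok]
  attr(lab, "invalid_cycle") <- !is.na(sc) & !cycles$valid[ifelse(is.na(sc), 1L, sc)]
  lab
}

#' Assign fixed-time cardiac bins
#'
#' Non-equidistant fixed-time gates measured from the previous R-peak, with
#' half-open lower-closed intervals at the division points (default
#' 50/120/420/550/1500 ms). Elapsed times of 1500 ms or more are rejected, as
#' are samples before the first or after the last trigger.
#'
#' @param times sample times in seconds.
#' @param triggers a `trigger_list` (sorted R-peak times, seconds).
#' @param division_ms strictly increasing division points in ms from the
#'   R-peak; the last value truncates the diastolic gate.
#' @return integer labels (1 = immediately post-R, `length(division_ms)` = the
#'   late-diastolic gate), `NA` = rejected.
#' @export
assign_cardiac_bins <- function(times, triggers,
                                division_ms = c(50, 120, 420, 550, 1500)) {
  trig <- as.numeric(triggers)
  if (length(trig) < 2L) stop("need at least 2 cardiac triggers")
  stopifnot(!is.unsorted(trig, strictly = TRUE),
            !is.unsorted(division_ms, strictly = TRUE))
  p <- findInterval(times, trig)
  lab <- rep(NA_integer_, length(times))
  ok <- p >= 1L & p < length(trig) & times < trig[length(trig)]
  tau <- (times - trig[pmax(p, 1L)]) * 1000
  nb <- length(division_ms)
  c_ <- findInterval(tau, c(0, division_ms[-nb]))
  ok <- ok & tau < division_ms[nb]
  lab[ok] <- c_[ok]
  lab
}

#' Combine respiratory and cardiac labels into dual-gate bins
#'
#' Dual bin `b = (c - 1) * 5 + r`, so that bin 25 is the end-diastolic,
#' end-expiratory gate and bins 21-25 form the diastolic set across
#' respiration. Rejected if either component is rejected.
#'
#' @param resp,cardiac integer label vectors on the same time base.
#' @param times optional sample times carried into the result.
#' @param n_resp number of respiratory bins.
#' @return `bin_assignment` data.frame with columns `time_s`, `r`, `c`, `b`
#'   and attribute `invalid_cycle` when the respiratory labels carried one.
#' @export
combine_dual <- function(resp, cardiac, times = NULL, n_resp = 5L) {
  if (length(resp) != length(cardiac)) {
    stop("misaligned time bases: respiratory and cardiac label streams differ in length")
  }
  b <- (cardiac - 1L) * n_resp + resp
  out <- data.frame(time_s = if (is.null(times)) seq_along(resp) else times,
                    r = as.integer(resp), c = as.integer(cardiac), b = as.integer(b))
  attr(out, "invalid_cycle") <- attr(resp, "invalid_cycle")
  class(out) <- c("bin_assignment", class(out))
  out
}

#' Dwell-fraction bookkeeping for a dual-gate assignment
#'
#' Fractions are of all samples, so per-bin fractions plus the rejected
#' fraction sum to one exactly. The DG fraction is the bin-25 dwell; the MoCo
#' fraction is the sum over the diastolic set (bins 21-25).
#'
#' @param assignment a `bin_assignment`.
#' @param n_total total number of dual bins.
#' @return `data_fraction_report`: list with `bin_fractions` (length 25),
#'   `rejected_fraction`, `invalid_cycle_loss`, `dg_fraction`,
#'   `moco_fraction`.
#' @export
data_fractions <- function(assignment, n_total = 25L) {
  stopifnot(inherits(assignment, "bin_assignment"), nrow(assignment) > 0L)
  n <- nrow(assignment)
  bf <- tabulate(assignment$b, nbins = n_total) / n
  rej <- sum(is.na(assignment$b)) / n
  inv <- attr(assignment, "invalid_cycle")
  structure(list(
    bin_fractions = bf,
    rejected_fraction = rej,
    invalid_cycle_loss = if (is.null(inv)) NA_real_ else mean(inv),
    dg_fraction = bf[n_total],
    moco_fraction = sum(bf[(n_total - 4L):n_total])
  ), class = "data_fraction_report")
}

#' @export
print.data_fraction_report <- function(x, ...) {
  cat(sprintf("Dual-gate data fractions: DG (bin 25) %.2f%%, MoCo (bins 21-25) %.2f%%\n",
              100 * x$dg_fraction, 100 * x$moco_fraction))
  cat(sprintf("  rejected %.2f%%, invalid-cycle loss %.2f%%\n",
              100 * x$rejected_fraction, 100 * x$invalid_cycle_loss))
  invisible(x)
}

#' One-call dual-gating of a trace + trigger pair
#'
#' Convenience wrapper running cycle detection, thresholding, respiratory and
#' cardiac labelling and the dual combination on the trace's own time base.
#'
#' @inheritParams detect_cycles
#' @inheritParams assign_cardiac_bins
#' @param n_bins respiratory bins.
#' @return list with `cycles`, `thresholds`, `assignment`, `fractions`.
#' @export
dual_gate <- function(trace, triggers, division_ms = c(50, 120, 420, 550, 1500),
                      n_bins = 5L,
                      validity_rule = list(period_factor = c(0.5, 2),
                                           range_factor = 0.3)) {
  cycles <- detect_cycles(trace, validity_rule)
  thr <- compute_thresholds(cycles, n_bins)
  r <- assign_respiratory_bins(trace, cycles, thr, n_bins)
  cc <- assign_cardiac_bins(trace$time_s, triggers, division_ms)
  asg <- combine_dual(r, cc, times = trace$time_s, n_resp = n_bins)
  list(cycles = cycles, thresholds = thr, assignment = asg,
       fractions = data_fractions(asg, n_bins * length(division_ms)))
}

#' Write a bin assignment as CSV
#' @param assignment `bin_assignment`; `path` file path.
#' @param path output path.
#' @export
write_assignment_csv <- function(assignment, path) {
  utils::write.csv(as.data.frame(assignment), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
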