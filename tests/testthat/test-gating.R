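noiseless_trace <- function(n_cycles = 30, period = 5) {
  generate_respiratory_trace(n_cycles * period, period, 0, 10, 0, 0, 0, seed = 1)
}

test_that("cycle detection: counts, degenerate input, corrupted-cycle flags", {
  tr <- noiseless_trace(12)
  cy <- detect_cycles(tr)
  # interior minima only: the trace's boundary minima at t = 0 and t = 60
  # have no neighbour on one side, so 11 interior minima delimit 10 cycles
  expect_equal(nrow(cy), 10L)
  expect_true(all(cy$valid))
  expect_true(all(diff(cy$start_s) > 0))

  ramp <- new_t <- seq(0, 60, by = 0.04)
  expect_error(detect_cycles(dualgate:::new_resp_trace(new_t, new_t)),
               "fewer than 2")

  # flags agree with the generator on every matched cycle (frozen seed)
  trc <- generate_respiratory_trace(500, 5, 0, 10, 0, 0,
                                    invalid_cycle_rate = 0.14, seed = 99)
  info <- attr(trc, "cycle_info")
  cy2 <- detect_cycles(trc)
  expect_equal(sum(!cy2$valid), 10L)
  mid <- (cy2$start_s + cy2$end_s) / 2
  gen_idx <- findInterval(mid, info$start_s)
  expect_identical(!cy2$valid, info$corrupted[gen_idx])
})

test_that("thresholds follow the mean+SD / mean rule", {
  tr <- noiseless_trace(12)
  th <- compute_thresholds(detect_cycles(tr))
  expect_equal(th$a_max, 10, tolerance = 1e-3)   # all maxima equal -> SD 0
  expect_equal(th$a_min, 0, tolerance = 1e-6)
  expect_equal(th$edges, seq(th$a_min, th$a_max, length.out = 6))

  # hand-computed with the sample-SD convention: maxima {8,10,12} (SD 2),
  # minima {0,1,2}
  cs <- data.frame(start_s = c(0, 5, 10), end_s = c(5, 10, 15),
                   period_s = 5, amp_max = c(8, 10, 12), amp_min = c(0, 1, 2),
                   valid = TRUE)
  class(cs) <- c("cycle_set", class(cs))
  th2 <- compute_thresholds(cs)
  expect_equal(th2$a_max, 12)
  expect_equal(th2$a_min, 1)

  cs1 <- cs[1, , drop = FALSE]
  class(cs1) <- c("cycle_set", class(cs1))
  expect_error(compute_thresholds(cs1), "at least 2 valid")
})

test_that("respiratory bin boundaries: clip below, reject above, occupancy", {
  tr <- noiseless_trace(30)
  cy <- detect_cycles(tr)
  th <- compute_thresholds(cy)
  r <- assign_respiratory_bins(tr, cy, th)
  # end-expiratory occupancy: closed form arccos(0.6)/pi = 29.52% of a period
  occ <- 100 * mean(r[!is.na(r)] == 5)
  expect_lt(abs(occ - 100 * acos(0.6) / pi), 0.5)

  # explicit boundary behaviour on a synthetic cycle set
  th3 <- structure(list(a_max = 10, a_min = 2, edges = seq(2, 10, length.out = 6)),
                   class = "gating_thresholds")
  tsyn <- dualgate:::new_resp_trace(seq(0, 0.5, by = 0.1),
                                    c(2, 1.2, 10, 10 + 1e-9, 6, 3.9))
  cyn <- data.frame(start_s = 0, end_s = 0.6, period_s = 0.6,
                    amp_max = 10, amp_min = 1.2, valid = TRUE)
  class(cyn) <- c("cycle_set", class(cyn))
  attr(cyn, "sample_cycle") <- rep(1L, 6)
  lab <- assign_respiratory_bins(tsyn, cyn, th3)
  expect_identical(lab[1], 5L)          # exactly a_min -> bottom bin
  expect_identical(lab[2], 5L)          # below a_min -> clipped into bottom
  expect_identical(lab[3], 1L)          # exactly a_max -> top bin
  expect_true(is.na(lab[4]))            # above a_max -> rejected
  expect_identical(lab[5], 3L)
  expect_identical(lab[6], 4L)
})

test_that("cardiac bins follow the fixed-time division", {
  tg <- new_trigger_list <- dualgate:::new_trigger_list(seq(0, 10, by = 1))
  tau_ms <- c(0, 49.9, 50, 119, 120, 300, 419, 420, 549, 550, 999)
  lab <- assign_cardiac_bins(tau_ms / 1000, tg)
  expect_identical(lab, c(1L, 1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 5L, 5L))
  # before first / after last trigger rejected
  lab2 <- assign_cardiac_bins(c(-0.5, 10.2), tg)
  expect_true(all(is.na(lab2)))
  # tau >= 1500 ms rejected even inside a long RR
  tg2 <- dualgate:::new_trigger_list(c(0, 2))
  expect_true(is.na(assign_cardiac_bins(1.6, tg2)))
  expect_identical(assign_cardiac_bins(1.4, tg2), 5L)
  # constant RR 1000 ms -> diastolic dwell = 45%
  tg3 <- dualgate:::new_trigger_list(seq(0, 600, by = 1))
  # half-step offset keeps samples off the bin edges, where floating-point
  # jitter in t*1000 would flip the label
  tt <- seq(0.005, 599.99, by = 0.01)
  lab3 <- assign_cardiac_bins(tt, tg3)
  expect_equal(mean(lab3[!is.na(lab3)] == 5L), 0.45, tolerance = 1e-3)
  expect_error(assign_cardiac_bins(1, dualgate:::new_trigger_list(numeric(0))),
               "at least 2")
})

test_that("dual combination and numbering anchors", {
  expect_equal(combine_dual(5L, 5L)$b, 25L)     # end-diastolic end-expiratory
  expect_equal(combine_dual(1L, 5L)$b, 21L)     # peak-inspiration diastolic
  expect_equal(combine_dual(1L, 1L)$b, 1L)
  expect_true(is.na(combine_dual(NA_integer_, 5L)$b))
  expect_true(is.na(combine_dual(3L, NA_integer_)$b))
  expect_error(combine_dual(c(1L, 2L), 1L), "misaligned")
  # b in 21..25 <=> c == 5; b == 25 <=> c == 5 and r == 5
  g <- expand.grid(r = 1:5, c = 1:5)
  b <- combine_dual(g$r, g$c)$b
  expect_setequal(b, 1:25)
  expect_identical(b >= 21 & b <= 25, g$c == 5L)
  expect_identical(b == 25L, g$c == 5L & g$r == 5L)
})

test_that("data fractions conserve mass and order DG <= MoCo", {
  tr <- generate_respiratory_trace(400, seed = 3)
  tg <- generate_cardiac_triggers(max(tr$time_s), seed = 4)
  out <- dual_gate(tr, tg)
  fr <- out$fractions
  expect_equal(sum(fr$bin_fractions) + fr$rejected_fraction, 1)
  expect_true(all(fr$bin_fractions >= 0 & fr$bin_fractions <= 1))
  expect_gte(fr$moco_fraction, fr$dg_fraction)
  expect_equal(fr$dg_fraction, fr$bin_fractions[25])
  expect_equal(fr$moco_fraction, sum(fr$bin_fractions[21:25]))
  # uniform labels -> each bin 1/25
  asg <- combine_dual(rep(1:5, 5), rep(1:5, each = 5))
  expect_true(all(abs(data_fractions(asg)$bin_fractions - 1 / 25) < 1e-12))
})

test_that("independent gating signals factorize bin 25", {
  tr <- noiseless_trace(100)
  tg <- generate_cardiac_triggers(max(tr$time_s), seed = 8)
  out <- dual_gate(tr, tg)
  asg <- out$assignment
  ok <- !is.na(asg$b)
  p_r5 <- mean(asg$r[ok] == 5)
  p_c5 <- mean(asg$c[ok] == 5)
  p_25 <- mean(asg$b[ok] == 25)
  expect_lt(abs(p_25 - p_r5 * p_c5), 0.02)
})

test_that("labels are invariant under affine amplitude rescaling", {
  tr <- generate_respiratory_trace(300, period_jitter = 0.08,
                                   amplitude_jitter = 0.15, seed = 17)
  tr2 <- dualgate:::new_resp_trace(tr$time_s, 3.7 * tr$amplitude + 11,
                                   attr(tr, "cycle_info"))
  lab1 <- with(dual_gate(tr, generate_cardiac_triggers(max(tr$time_s), seed = 18)),
               assignment$r)
  lab2 <- with(dual_gate(tr2, generate_cardiac_triggers(max(tr$time_s), seed = 18)),
               assignment$r)
  expect_identical(lab1, lab2)
})

test_that("vectorized labelers match a brute-force per-sample oracle", {
  tr <- generate_respiratory_trace(200, period_jitter = 0.08,
                                   amplitude_jitter = 0.15,
                                   invalid_cycle_rate = 0.1, seed = 55)
  tg <- generate_cardiac_triggers(max(tr$time_s), seed = 56)
  cy <- detect_cycles(tr)
  th <- compute_thresholds(cy)
  r_fast <- assign_respiratory_bins(tr, cy, th)
  c_fast <- assign_cardiac_bins(tr$time_s, tg)

  sc <- attr(cy, "sample_cycle")
  edges <- th$edges
  r_slow <- rep(NA_integer_, nrow(tr))
  for (i in seq_len(nrow(tr))) {
    ci <- sc[i]
    if (is.na(ci) || !cy$valid[ci]) next
    a <- tr$amplitude[i]
    if (a > th$a_max) next
    a <- max(a, th$a_min)
    for (k in 1:5) {
      hi <- if (k == 5) edges[6] + 1e-12 else edges[k + 1]
      if (a >= edges[k] && a < hi) { r_slow[i] <- 6L - k; break }
    }
  }
  expect_identical(r_fast, r_slow, ignore_attr = TRUE)

  div <- c(50, 120, 420, 550, 1500)
  trg <- as.numeric(tg)
  c_slow <- rep(NA_integer_, nrow(tr))
  for (i in seq_len(nrow(tr))) {
    t <- tr$time_s[i]
    if (t < trg[1] || t >= trg[length(trg)]) next
    p <- max(which(trg <= t))
    tau <- (t - trg[p]) * 1000
    if (tau >= div[5]) next
    lo <- c(0, div[1:4])
    for (k in 1:5) if (tau >= lo[k] && tau < div[k]) { c_slow[i] <- k; break }
  }
  expect_identical(c_fast, c_slow)
})
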