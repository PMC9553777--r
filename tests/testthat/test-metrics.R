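test_that("SUV normalization: unit case, decay, patient-A arithmetic", {
  m0 <- subject_meta(305, 0, 81)
  expect_equal(compute_suv(3.765, m0), 1, tolerance = 1e-3)
  # uniform C = D/W -> SUV identically 1
  mm <- subject_meta(400, 0, 80)
  c_unit <- 400 * 1000 / (80 * 1000)
  expect_equal(compute_suv(c_unit, mm), 1)
  # zero delay -> no decay correction; 1 half-life halves D_corr, doubles SUV
  m1 <- subject_meta(305, 109.77, 81)
  expect_equal(compute_suv(3.765, m1), 2, tolerance = 1e-3)
  expect_error(subject_meta(dose_MBq = 0), "positive")
  # round trip with the internal inverse
  expect_equal(dualgate:::suv_to_activity(compute_suv(5.1, m0), m0), 5.1)
})

test_that("VOI statistics: constants, two-voxel SD, volume bookkeeping", {
  v <- as_volume(array(2.5, c(6, 6, 6)), 2.73)
  mask <- as_volume(array(1, c(6, 6, 6)), 2.73)
  st <- voi_statistics(v, mask)
  expect_equal(st$mean, 2.5)
  expect_equal(st$sd, 0)
  v2 <- v; v2[1, 1, 1] <- 1; v2[2, 1, 1] <- 3
  m2 <- as_volume(array(0, c(6, 6, 6)), 2.73); m2[1:2, 1, 1] <- 1
  st2 <- voi_statistics(v2, m2)
  expect_equal(st2$mean, 2)
  expect_equal(st2$sd, sqrt(2))
  # an 11.0 cm^3 region at 2.73 mm isotropic
  n_vox <- round(11.0 * 1000 / 2.73^3)
  m3 <- as_volume(array(0, c(20, 20, 20)), 2.73)
  m3[seq_len(n_vox)] <- 1
  st3 <- voi_statistics(as_volume(array(1, c(20, 20, 20)), 2.73), m3)
  expect_lt(abs(st3$volume_cm3 - 11.0), 2.73^3 / 1000)
  expect_error(voi_statistics(v, as_volume(array(0, c(6, 6, 6)), 2.73)),
               "empty mask")
})

test_that("quality ratios follow their defining algebra", {
  myo <- structure(list(mean = 2, sd = 0.6), class = "voi_stats")
  blood <- structure(list(mean = 1, sd = 0.5), class = "voi_stats")
  q <- image_quality_metrics(myo, blood)
  expect_equal(q$CR, 2)
  expect_equal(q$SNR, 4)
  expect_equal(q$CV_pct, 30)
  expect_equal(q$CNR, 2)
  # homogeneity: global scaling by k leaves CR and CV unchanged and scales
  # nothing in the SNR/CNR ratio
  k <- 3.7
  myo_k <- structure(list(mean = 2 * k, sd = 0.6 * k), class = "voi_stats")
  blood_k <- structure(list(mean = 1 * k, sd = 0.5 * k), class = "voi_stats")
  qk <- image_quality_metrics(myo_k, blood_k)
  expect_equal(qk$CR, q$CR)
  expect_equal(qk$CV_pct, q$CV_pct)
  expect_equal(qk$CNR / qk$SNR, q$CNR / q$SNR)
  # myo mean = blood mean -> CNR 0
  q0 <- image_quality_metrics(structure(list(mean = 1, sd = 0.2),
                                        class = "voi_stats"), blood)
  expect_equal(q0$CNR, 0)
  # a zero blood SD invalidates both SNR and CNR, with one warning each
  expect_warning(expect_warning(
    qna <- image_quality_metrics(myo, structure(
      list(mean = 1, sd = 0), class = "voi_stats")), "zero denominator"))
  expect_true(is.na(qna$SNR) && is.na(qna$CNR))
})

test_that("wall thickness: rectangle, Gaussian closed form, symmetry", {
  n <- 64
  rect <- array(0, c(n, n, 8)); rect[24:39, , ] <- 1    # 16 mm at 1 mm voxels
  vr <- as_volume(rect, 1)
  expect_equal(as.numeric(myocardial_wall_thickness(vr, c(0, 10, 3),
                                                    c(63, 10, 3), 0.5)), 16)
  sg <- 7.08
  prof <- exp(-((seq_len(n) - 1) - 31.5)^2 / (2 * sg^2))
  ga <- array(rep(prof, times = n * 8), c(n, n, 8))
  vg <- as_volume(ga, 1)
  mwt <- myocardial_wall_thickness(vg, c(0, 10, 3), c(63, 10, 3), 0.25)
  expect_lt(abs(as.numeric(mwt) - 2.3548 * sg), 0.5)
  # symmetric profile: crossings equidistant from the peak
  p <- attr(mwt, "profile")
  pk <- p$s_mm[which.max(p$value)]
  expect_equal(pk, 31.5, tolerance = 0.3)
  # smoothing never decreases the FWHM
  vg_sm <- gaussian_postfilter(vg, 6)
  expect_gte(as.numeric(myocardial_wall_thickness(vg_sm, c(0, 10, 3),
                                                  c(63, 10, 3), 0.25)),
             as.numeric(mwt) - 1e-6)
  # a profile that never crosses the half maximum errors out
  flat <- as_volume(array(1, c(n, n, 8)), 1)
  expect_error(myocardial_wall_thickness(flat, c(0, 10, 3), c(63, 10, 3)),
               "peak")
})

test_that("phantom wall FWHM matches the 1-D convolution oracle", {
  sp <- mid_spec()
  fr <- render_phantom_frame(sp, 0, 0)
  sm <- gaussian_postfilter(fr$activity, 6)
  cc <- (sp$shape - 1) / 2 * sp$spacing
  step <- 0.25
  measured <- as.numeric(myocardial_wall_thickness(sm, cc, cc + c(70, 0, 0), step))
  # oracle: the raw (unfiltered) voxelized profile along the same ray,
  # convolved in 1-D with the same discrete Gaussian the filter uses
  raw <- myocardial_wall_thickness(fr$activity, cc, cc + c(70, 0, 0), step)
  prof <- attr(raw, "profile")
  k <- dualgate:::gauss_kernel((6 / 2.3548) / step)
  v <- as.numeric(stats::filter(prof$value, k, sides = 2))
  sel <- !is.na(v)
  xs <- prof$s_mm[sel]; vs <- v[sel]
  pk <- which.max(vs)
  base <- max(vs[1], vs[length(vs)])
  half <- base + 0.5 * (vs[pk] - base)
  li <- max(which(vs[1:pk] < half))
  ri <- pk + min(which(vs[(pk + 1):length(vs)] < half))
  oracle <- (xs[ri] - xs[li])
  expect_lt(abs(measured - oracle), 0.5)
})

test_that("blood-pool noise scales as 1 / sqrt(dwell x budget)", {
  sp <- small_spec(resp_amplitude_mm = 0, contraction_frac = 0)
  tr <- generate_respiratory_trace(240, period_jitter = 0,
                                   amplitude_jitter = 0,
                                   invalid_cycle_rate = 0, seed = 71)
  tg <- generate_cardiac_triggers(max(tr$time_s), sd_hr = 0, seed = 72)
  ref <- render_phantom_frame(sp, 0, 0)
  blood <- erode_mask(ref$mask_blood, 1) > 0.5
  sds <- vapply(c(1e5, 9e5), function(budget) {
    st <- simulate_gated_study(sp, tr, tg, counts_budget = budget, seed = 73)
    sd(st$bins[[25]]$noisy[blood])
  }, numeric(1))
  expect_equal(sds[1] / sds[2], 3, tolerance = 0.35)
})

test_that("evaluate_methods: identical inputs, JSON round trip", {
  sp <- small_spec()
  fr <- render_phantom_frame(sp, 0, 0)
  meta <- subject_meta()
  img <- dualgate:::suv_to_activity(gaussian_postfilter(fr$activity, 6), meta)
  cc <- (sp$shape - 1) / 2 * sp$spacing
  profile <- list(p0_mm = cc, p1_mm = cc + c(65, 0, 0))
  rep_ <- evaluate_methods(list(A = img, B = img), fr$mask_myo,
                           erode_mask(fr$mask_blood, 1), meta, profile)
  expect_equal(unlist(rep_[1, -1]), unlist(rep_[2, -1]))
  path <- tempfile(fileext = ".json")
  write_quality_report_json(rep_, path)
  back <- read_quality_report_json(path)
  expect_equal(as.data.frame(unclass(back)), as.data.frame(unclass(rep_)),
               tolerance = 1e-12)
})

test_that("mask morphology: erosion shrinks, closing fills", {
  m <- as_volume(array(0, c(12, 12, 12)), 1)
  m[3:10, 3:10, 3:10] <- 1
  er <- erode_mask(m, 1)
  expect_lt(sum(er), sum(m))
  expect_true(all(m[er > 0.5] == 1))
  holey <- m; holey[6, 6, 6] <- 0
  cl <- close_mask(holey, 1)
  expect_equal(cl[6, 6, 6], 1)
})
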