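geom64 <- function() recon_geometry(64, 2.73, 96)

test_that("projector matches the analytic Radon transform of a disk", {
  g <- geom64()
  R <- 40
  disk <- aa_disk(64, 2.73, R)
  sino <- forward_project_attenuated(disk, NULL, g)
  s <- g$offsets
  chord <- 2 * sqrt(pmax(R^2 - s^2, 0))
  sel <- abs(s) < 0.8 * R
  for (a in c(1L, 25L, 50L, 96L)) {
    expect_lt(max(abs(sino[sel, a] - chord[sel]) / chord[sel]), 0.02)
  }
  # zero activity -> zero sinogram
  z <- forward_project_attenuated(matrix(0, 64, 64), NULL, g)
  expect_equal(max(abs(z)), 0)
  expect_error(forward_project_attenuated(disk, -disk, g), "non-negative")
})

test_that("central ray of a point source is attenuated by exp(-2 mu R)", {
  g <- geom64()
  R <- 40; mu_val <- 0.096
  mu <- aa_disk(64, 2.73, R) * mu_val
  ps <- matrix(0, 64, 64); ps[32:33, 32:33] <- 1
  s0 <- forward_project_attenuated(ps, NULL, g)
  s1 <- forward_project_attenuated(ps, mu, g)
  ctr <- which.max(s0[, 1])
  expect_equal(s1[ctr, 1] / s0[ctr, 1], exp(-2 * mu_val * R / 10),
               tolerance = 0.03)
})

test_that("projector adjoint identity holds to 1e-6", {
  g <- recon_geometry(32, 2.73, 24)
  M <- dualgate:::system_matrix(g)
  set.seed(1)
  x <- rnorm(ncol(M)); y <- rnorm(nrow(M))
  lhs <- sum(as.numeric(M %*% x) * y)
  rhs <- sum(x * as.numeric(Matrix::crossprod(M, y)))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
})

test_that("OSEM reconstructs a noise-free disk and is homogeneous", {
  g <- geom64()
  disk <- aa_disk(64, 2.73, 40)
  mu <- disk * 0.096
  sino <- forward_project_attenuated(disk, mu, g)
  cfg <- recon_config(2, 24, n = 64, n_angles = 96)
  rec <- osem_reconstruct(sino, mu, cfg)
  cc <- (64 - 1) / 2 * 2.73
  xy <- expand.grid(x = (1:64 - 1) * 2.73, y = (1:64 - 1) * 2.73)
  fov <- matrix((xy$x - cc)^2 + (xy$y - cc)^2 <= (0.9 * cc)^2, 64, 64)
  nrmse <- sqrt(mean((rec[fov] - disk[fov])^2)) / mean(disk[disk > 0.5])
  expect_lt(nrmse, 0.10)
  # EM homogeneity with uniform init: scaling the data scales the estimate
  sino_k <- sino * 3.7
  attr(sino_k, "geometry") <- g
  class(sino_k) <- class(sino)
  rec_k <- osem_reconstruct(sino_k, mu, cfg)
  expect_equal(rec_k, 3.7 * rec, tolerance = 1e-10)
  # all-zero sinogram -> zero image, no division error
  z <- forward_project_attenuated(matrix(0, 64, 64), NULL, g)
  expect_equal(max(abs(osem_reconstruct(z, NULL, cfg))), 0)
})

test_that("OSEM with 1 subset equals hand-rolled MLEM; likelihood increases", {
  g <- recon_geometry(48, 2.73, 48)
  act <- aa_disk(48, 2.73, 25) + 0.5 * aa_disk(48, 2.73, 12)
  mu <- aa_disk(48, 2.73, 40) * 0.096
  sino <- forward_project_attenuated(act, mu, g)
  # independent MLEM oracle written from the forward operator
  M <- dualgate:::system_matrix(g)
  att <- dualgate:::ray_attenuation(mu, g)
  y <- as.numeric(sino)
  x <- rep(1, 48 * 48)
  sens <- as.numeric(Matrix::crossprod(M, att))
  ll <- numeric(0)
  for (it in 1:3) {
    yh <- att * as.numeric(M %*% x)
    ll <- c(ll, sum(ifelse(y > 0, y * log(pmax(yh, 1e-300)), 0) - yh))
    r <- ifelse(yh > 1e-12, y / yh, 0)
    x <- ifelse(sens > 1e-12,
                x * as.numeric(Matrix::crossprod(M, att * r)) / sens, 0)
  }
  rec <- osem_reconstruct(sino, mu, recon_config(3, 1, n = 48, n_angles = 48))
  expect_equal(as.numeric(rec), x, tolerance = 1e-12)
  expect_true(all(diff(ll) > -1e-6))     # monotone on noise-free data
})

test_that("mismatched attenuation map biases the ROI more than the matched map", {
  g <- recon_geometry(48, 2.73, 48)
  act <- aa_disk(48, 2.73, 20)
  mu <- aa_disk(48, 2.73, 40) * 0.096
  mu_shift <- rbind(mu[-(1:4), ], mu[1:4, ])    # ~11 mm misalignment
  sino <- forward_project_attenuated(act, mu, g)
  cfg <- recon_config(2, 24, n = 48, n_angles = 48)
  rec_ok <- osem_reconstruct(sino, mu, cfg)
  rec_bad <- osem_reconstruct(sino, mu_shift, cfg)
  roi <- act > 0.5
  bias_ok <- abs(mean(rec_ok[roi]) - mean(act[roi]))
  bias_bad <- abs(mean(rec_bad[roi]) - mean(act[roi]))
  expect_gt(bias_bad, bias_ok)
})

test_that("attenuation map builder: average, arithmetic, gated phase", {
  sp <- small_spec()
  f1 <- render_phantom_frame(sp, 0.1, 0)
  mu_list <- lapply(c(0.9, 0.7, 0.5, 0.3, 0.1),
                    function(l) render_phantom_frame(sp, l, 0)$mu)
  same <- build_attenuation_map(list(f1$mu, f1$mu, f1$mu), "cine_average")
  expect_volume_equal(same, f1$mu)
  two <- build_attenuation_map(list(as_volume(array(0.03, c(2, 2, 2)), 1),
                                    as_volume(array(0.096, c(2, 2, 2)), 1)),
                               "cine_average")
  expect_equal(unique(as.numeric(two)), 0.063)
  # gated:5 equals the end-expiratory rendering exactly
  g5 <- build_attenuation_map(mu_list, "gated", bin = 5)
  expect_volume_equal(g5, render_phantom_frame(sp, 0.1, 0)$mu)
  expect_error(build_attenuation_map(mu_list, "gated", bin = 9), "missing")
})

test_that("Gaussian post-filter: identity, FWHM, mass conservation", {
  sp <- c(32, 32, 32)
  img <- as_volume(array(0, sp), 2)
  img[16, 16, 16] <- 1
  expect_identical(gaussian_postfilter(img, 0), img)
  sm <- gaussian_postfilter(img, 6)
  expect_equal(sum(sm), 1, tolerance = 1e-3)     # interior impulse conserved
  prof <- sm[, 16, 16]
  pk <- which.max(prof)
  half <- prof[pk] / 2
  li <- max(which(prof[1:(pk - 1)] < half))
  ri <- pk + min(which(prof[(pk + 1):32] < half)) - 1
  xl <- (li + (half - prof[li]) / (prof[li + 1] - prof[li]) - 1) * 2
  xr <- (ri - (half - prof[ri]) / (prof[ri - 1] - prof[ri]) - 1) * 2
  expect_lt(abs((xr - xl) - 6), 1)               # FWHM within half a voxel
})

test_that("attenuation sensitivity is in (0,1] and phase ratio is near 1", {
  sp <- small_spec()
  f0 <- render_phantom_frame(sp, 0, 0)
  s0 <- attenuation_sensitivity(f0$mu, 8)
  expect_true(all(s0 > 0) && all(s0 <= 1))
  body <- f0$activity > 0
  expect_true(all(s0[body] < 1))                 # attenuation reduces sensitivity
  f9 <- render_phantom_frame(sp, 0.9, 0)
  s9 <- attenuation_sensitivity(f9$mu, 8)
  ratio <- s0[f0$mask_myo > 0.5] / s9[f0$mask_myo > 0.5]
  expect_true(all(ratio > 0.85 & ratio < 1.15))  # few-percent first-order bias
  expect_gt(max(abs(ratio - 1)), 0.005)          # ... but not trivially 1
})
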