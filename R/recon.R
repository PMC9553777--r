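# Cache of system matrices keyed by geometry (they are expensive to build).
.recon_cache <- new.env(parent = emptyenv())

#' Parallel-beam geometry for the 2D projector
#'
#' @param n image size (n x n pixels).
#' @param spacing_mm pixel size, mm.
#' @param n_angles projection angles over `[0, pi)`.
#' @param n_offsets radial bins (default `n`, one per pixel width).
#' @return a `recon_geometry` list.
#' @export
recon_geometry <- function(n, spacing_mm = 2.73, n_angles = 96L, n_offsets = n) {
  stopifnot(n >= 8, n_angles >= 2)
  structure(list(n = as.integer(n), spacing = spacing_mm,
                 n_angles = as.integer(n_angles),
                 n_offsets = as.integer(n_offsets),
                 angles = (seq_len(n_angles) - 1) * pi / n_angles,
                 offsets = ((seq_len(n_offsets)) - (n_offsets + 1) / 2) * spacing_mm),
            class = "recon_geometry")
}

# Sparse system matrix (rays x pixels) by Joseph-style sampling: each ray is
# sampled at half-pixel steps and bilinear weights are accumulated. Row order:
# offset-major within angle. Weights carry the step length (mm).
system_matrix <- function(geom) {
  key <- sprintf("%d_%g_%d_%d", geom$n, geom$spacing, geom$n_angles, geom$n_offsets)
  if (!is.null(.recon_cache[[key]])) return(.recon_cache[[key]])
  n <- geom$n; sp <- geom$spacing
  cc <- (n - 1) / 2 * sp
  h <- sp / 2
  half_len <- n * sp * 0.75
  tt <- seq(-half_len, half_len, by = h)
  ii <- jj <- ww <- list()
  for (ai in seq_len(geom$n_angles)) {
    th <- geom$angles[ai]
    dx <- cos(th); dy <- sin(th)
    nx <- -sin(th); ny <- cos(th)
    s <- rep(geom$offsets, each = length(tt))
    t <- rep(tt, times = geom$n_offsets)
    px <- cc + s * nx + t * dx
    py <- cc + s * ny + t * dy
    ci <- px / sp + 1; cj <- py / sp + 1
    keep <- ci >= 1 & ci <= n & cj >= 1 & cj <= n
    ray <- (ai - 1L) * geom$n_offsets + rep(seq_len(geom$n_offsets), each = length(tt))
    ci <- ci[keep]; cj <- cj[keep]; ray <- ray[keep]
    i0 <- pmin(floor(ci), n - 1L); fi <- ci - i0
    j0 <- pmin(floor(cj), n - 1L); fj <- cj - j0
    ii[[ai]] <- rep(ray, 4L)
    jj[[ai]] <- c(i0 + (j0 - 1) * n, i0 + 1 + (j0 - 1) * n,
                  i0 + j0 * n, i0 + 1 + j0 * n)
    ww[[ai]] <- h * c((1 - fi) * (1 - fj), fi * (1 - fj),
                      (1 - fi) * fj, fi * fj)
  }
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                            dims = c(geom$n_angles * geom$n_offsets, n * n))
  .recon_cache[[key]] <- M
  M
}

#' Attenuated forward projection of a 2D activity slice
#'
#' Line integrals of activity weighted by `exp(-integral of mu)` over the full
#' chord (PET coincidence attenuation: the factor depends on the ray, not on
#' the emission point). `mu` in 1/cm; lengths in mm are converted.
#'
#' @param activity n x n matrix (values >= 0).
#' @param mu n x n attenuation slice, 1/cm; `NULL` for no attenuation.
#' @param geom `recon_geometry`.
#' @return `dg_sinogram`: matrix (offsets x angles) with the geometry attached.
#' @export
forward_project_attenuated <- function(activity, mu, geom) {
  stopifnot(all(dim(activity) == c(geom$n, geom$n)))
  if (!is.null(mu)) {
    stopifnot(all(dim(mu) == c(geom$n, geom$n)))
    if (any(mu < 0)) stop("mu must be non-negative")
  }
  M <- system_matrix(geom)
  y <- as.numeric(M %*% as.numeric(activity))
  if (!is.null(mu)) {
    att <- exp(-0.1 * as.numeric(M %*% as.numeric(mu)))  # mm -> cm
    y <- att * y
  }
  out <- matrix(y, geom$n_offsets, geom$n_angles)
  attr(out, "geometry") <- geom
  class(out) <- c("dg_sinogram", class(out))
  out
}

# Ray attenuation factors for a mu slice (vector over rays, offset-major).
ray_attenuation <- function(mu, geom) {
  if (is.null(mu)) return(rep(1, geom$n_offsets * geom$n_angles))
  exp(-0.1 * as.numeric(system_matrix(geom) %*% as.numeric(mu)))
}

#' Reconstruction configuration
#'
#' @param iterations OSEM iterations.
#' @param subsets ordered subsets (angle-interleaved; must divide the angle
#'   count).
#' @param postfilter_fwhm_mm Gaussian post-filter FWHM.
#' @param n,fov_mm,n_angles reconstruction grid, field of view and angle count.
#' @export
recon_config <- function(iterations = 2L, subsets = 24L, postfilter_fwhm_mm = 6,
                         n = 128L, fov_mm = 350, n_angles = 192L) {
  stopifnot(iterations >= 1, subsets >= 1, n_angles %% subsets == 0)
  structure(list(iterations = as.integer(iterations),
                 subsets = as.integer(subsets),
                 postfilter_fwhm_mm = postfilter_fwhm_mm,
                 n = as.integer(n), fov_mm = fov_mm,
                 n_angles = as.integer(n_angles)),
            class = "recon_config")
}

#' OSEM reconstruction of one slice
#'
#' Multiplicative EM updates over angle-interleaved subsets (subset `i` takes
#' angles `i, i + subsets, ...`), uniform positive initialization. Attenuation
#' enters the system model through the per-ray factors of the supplied mu
#' slice, so correcting with a mismatched mu-map biases the estimate.
#'
#' @param sinogram `dg_sinogram` (non-negative).
#' @param mu attenuation slice used for correction (1/cm), or `NULL`.
#' @param config `recon_config` (only `iterations` and `subsets` are used; the
#'   grid comes from the sinogram's geometry).
#' @return reconstructed n x n activity slice.
#' @export
osem_reconstruct <- function(sinogram, mu = NULL, config = recon_config()) {
  geom <- attr(sinogram, "geometry")
  stopifnot(!is.null(geom), all(sinogram >= 0),
            geom$n_angles %% config$subsets == 0)
  M <- system_matrix(geom)
  att <- ray_attenuation(mu, geom)
  y <- as.numeric(sinogram)
  x <- rep(1, geom$n * geom$n)
  tiny <- 1e-12
  subset_rows <- lapply(seq_len(config$subsets), function(s) {
    ang <- seq(s, geom$n_angles, by = config$subsets)
    as.integer(outer(seq_len(geom$n_offsets), (ang - 1L) * geom$n_offsets, `+`))
  })
  for (it in seq_len(config$iterations)) {
    for (s in seq_len(config$subsets)) {
      rows <- subset_rows[[s]]
      Ms <- M[rows, , drop = FALSE]
      as_ <- att[rows]
      yhat <- as_ * as.numeric(Ms %*% x)
      ratio <- ifelse(yhat > tiny, y[rows] / yhat, 0)
      corr <- as.numeric(Matrix::crossprod(Ms, as_ * ratio))
      sens <- as.numeric(Matrix::crossprod(Ms, as_))
      x <- ifelse(sens > tiny, x * corr / sens, 0)
    }
  }
  matrix(x, geom$n, geom$n)
}

#' Build the attenuation map used for correction
#'
#' `cine_average` returns the dwell-weighted voxelwise mean over the phase
#' maps (the CINE-CT surrogate); `gated` returns the single map whose
#' respiratory bin matches `bin` (the 4D-CT surrogate, nearest-bin matching).
#'
#' @param mu_phases list of per-respiratory-phase mu volumes (index = bin).
#' @param mode `"cine_average"` or `"gated"`.
#' @param bin respiratory bin for `mode = "gated"`.
#' @param weights dwell weights for the average (default equal).
#' @return a mu volume.
#' @export
build_attenuation_map <- function(mu_phases, mode = c("cine_average", "gated"),
                                  bin = NULL, weights = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(mu_phases) >= 1L)
  if (mode == "gated") {
    if (is.null(bin) || bin < 1 || bin > length(mu_phases) ||
        is.null(mu_phases[[bin]])) {
      stop("requested attenuation phase bin missing")
    }
    return(mu_phases[[bin]])
  }
  w <- weights %||% rep(1 / length(mu_phases), length(mu_phases))
  stopifnot(length(w) == length(mu_phases))
  w <- w / sum(w)
  out <- Reduce(`+`, Map(function(m, wi) m * wi, mu_phases, w))
  attributes(out) <- attributes(mu_phases[[1]])
  out
}

#' Gaussian post-reconstruction filter
#'
#' Isotropic smoothing with `sigma = FWHM / 2.3548`, converted to voxels
#' through the image's spacing. `fwhm_mm = 0` is the identity.
#'
#' @param image 2D or 3D array (spacing attribute honoured, else 1 mm).
#' @param fwhm_mm filter full width at half maximum, mm.
#' @export
gaussian_postfilter <- function(image, fwhm_mm = 6) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(image)
  smooth_gaussian(image, sigma_mm = fwhm_mm / 2.3548)
}

#' Angular-mean chord attenuation sensitivity
#'
#' For each voxel, the mean over projection angles of
#' `exp(-integral of mu over the full chord through that voxel)` -- the
#' first-order per-voxel sensitivity that attenuation imposes on a 2D PET
#' slice. The ratio of the true phase's sensitivity to that of the mu-map used
#' for correction emulates, in image space, the quantitative bias of
#' reconstructing with a mismatched attenuation map.
#'
#' @param mu_vol 3D mu volume (1/cm); sensitivities are computed slice-wise.
#' @param n_angles number of angles averaged.
#' @return volume of per-voxel sensitivities in `(0, 1]`.
#' @export
attenuation_sensitivity <- function(mu_vol, n_angles = 12L) {
  d <- dim(mu_vol)
  sp <- spacing_of(mu_vol)
  out <- array(0, d)
  thetas <- (seq_len(n_angles) - 1) * pi / n_angles
  ones <- matrix(1, d[1], d[2])
  for (k in seq_len(d[3])) {
    sl <- mu_vol[, , k]
    acc <- matrix(0, d[1], d[2])
    wacc <- matrix(0, d[1], d[2])
    for (th in thetas) {
      rot <- rotate2d(sl, th)
      L <- colSums(rot) * sp[1] * 0.1              # chord integral, cm
      fac_rot <- matrix(exp(-L), d[1], d[2], byrow = TRUE)
      mrot <- rotate2d(ones, th)
      acc <- acc + rotate2d(fac_rot * mrot, -th)
      wacc <- wacc + rotate2d(mrot, -th)
    }
    out[, , k] <- ifelse(wacc > 0.5, acc / pmax(wacc, 0.5), 1)
  }
  as_volume(pmin(out, 1), sp)
}

#' Write / read a sinogram as TSV with a JSON geometry sidecar
#' @param sino `dg_sinogram`; `path` base path (`.tsv` written, plus
#'   `.json`).
#' @param path output path.
#' @export
write_sinogram <- function(sino, path) {
  utils::write.table(unclass(sino), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  g <- attr(sino, "geometry")
  jsonlite::write_json(g[c("n", "spacing", "n_angles", "n_offsets")],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  vals <- as.matrix(utils::read.table(path, sep = "\t"))
  g <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geom <- recon_geometry(g$n, g$spacing, g$n_angles, g$n_offsets)
  out <- matrix(as.numeric(vals), geom$n_offsets, geom$n_angles)
  attr(out, "geometry") <- geom
  class(out) <- c("dg_sinogram", class(out))
  out
}
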