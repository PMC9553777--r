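#' dualgate: dual-gated cardiac PET simulation, gating and motion correction
#'
#' See the package README and the methods vignette for the model, the gating
#' conventions (bin 25 = end-diastolic end-expiratory reference; bins 21-25 =
#' the diastolic set) and the coordinate convention (world mm, RAS, origin at
#' the centre of voxel `[1,1,1]`).
#'
#' @keywords internal
"_PACKAGE"

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not disturb
#' the caller's RNG stream. All stochastic operations in the package route
#' their randomness through this helper.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a spatial volume
#'
#' A volume is a numeric 3D array carrying a `spacing` attribute (mm per voxel
#' along each axis). World coordinates place the centre of voxel `[1,1,1]` at
#' the origin: `x_mm = (i - 1) * spacing[1]` and so on.
#'
#' @param a 3D array.
#' @param spacing numeric length-3 voxel spacing in mm (recycled if scalar).
#' @return the array with class `dg_volume` and a `spacing` attribute.
#' @export
as_volume <- function(a, spacing) {
  stopifnot(is.array(a), length(dim(a)) == 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  stopifnot(all(spacing > 0))
  attr(a, "spacing") <- spacing
  class(a) <- c("dg_volume", class(a))
  a
}

#' @export
print.dg_volume <- function(x, ...) {
  d <- dim(x)
  sp <- attr(x, "spacing")
  cat(sprintf("<dg_volume %dx%dx%d, spacing %.3gx%.3gx%.3g mm, range [%.4g, %.4g]>\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3], min(x), max(x)))
  invisible(x)
}

spacing_of <- function(a, default = c(1, 1, 1)) {
  sp <- attr(a, "spacing")
  if (is.null(sp)) default else rep_len(as.numeric(sp), 3L)
}

#' Discrete Gaussian kernel
#' @param sigma standard deviation in sample units; 0 gives the identity tap.
#' @keywords internal
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

# 1D convolution along dimension `dim` of a 2D/3D array, zero padding,
# implemented as shift-and-add (kernels here are short).
conv_dim <- function(a, w, dim) {
  nk <- length(w)
  if (nk == 1L) return(a * w)
  r <- (nk - 1L) %/% 2L
  d <- dim(a)
  out <- array(0, d)
  idx_full <- lapply(d, seq_len)
  for (t in seq_len(nk)) {
    off <- t - r - 1L
    n <- d[dim]
    src <- seq_len(n) + off
    keep <- src >= 1L & src <= n
    if (!any(keep)) next
    ia <- idx_full; ib <- idx_full
    ia[[dim]] <- which(keep)
    ib[[dim]] <- src[keep]
    out_part <- do.call(`[`, c(list(a), ib, list(drop = FALSE)))
    slice_assign(out, ia) <- do.call(`[`, c(list(out), ia, list(drop = FALSE))) + w[t] * out_part
  }
  out
}

`slice_assign<-` <- function(x, idx, value) {
  do.call(`[<-`, c(list(x), idx, list(value = value)))
}

#' Separable Gaussian smoothing of a 2D or 3D array
#'
#' @param a array (2D or 3D); a `spacing` attribute is honoured when
#'   `sigma_mm` is given.
#' @param sigma_vox per-axis standard deviation in voxels (recycled).
#' @param sigma_mm alternative: per-axis standard deviation in mm, converted
#'   through the array's spacing.
#' @return smoothed array, attributes preserved.
#' @export
smooth_gaussian <- function(a, sigma_vox = NULL, sigma_mm = NULL) {
  nd <- length(dim(a))
  stopifnot(nd %in% c(2L, 3L))
  if (!is.null(sigma_mm)) {
    sp <- spacing_of(a)[seq_len(nd)]
    sigma_vox <- rep_len(as.numeric(sigma_mm), nd) / sp
  }
  sigma_vox <- rep_len(as.numeric(sigma_vox), nd)
  out <- a
  att <- attributes(a)
  for (d in seq_len(nd)) {
    if (sigma_vox[d] > 0) out <- conv_dim(out, gauss_kernel(sigma_vox[d]), d)
  }
  attributes(out) <- att
  out
}

# Trilinear sampling of a 3D array at fractional voxel coordinates (1-based).
# Coordinates outside the grid return `fill`.
trilinear_at <- function(a, ci, cj, ck, fill = 0) {
  d <- dim(a)
  tol <- 1e-6    # coordinates within rounding error of the border are inside
  inb <- ci >= 1 - tol & ci <= d[1] + tol & cj >= 1 - tol & cj <= d[2] + tol &
    ck >= 1 - tol & ck <= d[3] + tol
  ci <- pmin(pmax(ci, 1), d[1]); cj <- pmin(pmax(cj, 1), d[2])
  ck <- pmin(pmax(ck, 1), d[3])
  i0 <- pmin(pmax(floor(ci), 1L), d[1] - 1L); fi <- ci - i0
  j0 <- pmin(pmax(floor(cj), 1L), d[2] - 1L); fj <- cj - j0
  k0 <- pmin(pmax(floor(ck), 1L), d[3] - 1L); fk <- ck - k0
  if (d[1] < 2L || d[2] < 2L || d[3] < 2L) stop("grid too small for interpolation")
  nx <- d[1]; nxy <- d[1] * d[2]
  base <- (i0) + (j0 - 1) * nx + (k0 - 1) * nxy
  v000 <- a[base];              v100 <- a[base + 1]
  v010 <- a[base + nx];         v110 <- a[base + nx + 1]
  v001 <- a[base + nxy];        v101 <- a[base + nxy + 1]
  v011 <- a[base + nx + nxy];   v111 <- a[base + nx + nxy + 1]
  out <- (1 - fk) * ((1 - fj) * ((1 - fi) * v000 + fi * v100) +
                       fj * ((1 - fi) * v010 + fi * v110)) +
    fk * ((1 - fj) * ((1 - fi) * v001 + fi * v101) +
            fj * ((1 - fi) * v011 + fi * v111))
  out[!inb] <- fill
  out
}

# Block-mean downsampling of a 3D array by integer factor f (spacing scales up).
downsample_block <- function(a, f) {
  if (f == 1L) return(a)
  d <- dim(a)
  nd <- floor(d / f)
  stopifnot(all(nd >= 2))
  sub <- a[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f), drop = FALSE]
  dim(sub) <- c(f, nd[1], f, nd[2], f, nd[3])
  out <- apply(sub, c(2L, 4L, 6L), mean)
  as_volume(out, spacing_of(a) * f)
}

# Trilinear upsampling of a 3D array onto a target grid with given spacing.
# Values (e.g. displacements in mm) are carried unchanged.
upsample_to <- function(a, target_dim, target_spacing) {
  sp <- spacing_of(a)
  g <- expand.grid(i = seq_len(target_dim[1]), j = seq_len(target_dim[2]),
                   k = seq_len(target_dim[3]))
  ci <- (g$i - 1) * target_spacing[1] / sp[1] + 1
  cj <- (g$j - 1) * target_spacing[2] / sp[2] + 1
  ck <- (g$k - 1) * target_spacing[3] / sp[3] + 1
  # clamp: sampling beyond the coarse grid edge extends the border value
  d <- dim(a)
  ci <- pmin(pmax(ci, 1), d[1]); cj <- pmin(pmax(cj, 1), d[2]); ck <- pmin(pmax(ck, 1), d[3])
  v <- trilinear_at(a, ci, cj, ck)
  as_volume(array(v, target_dim), target_spacing)
}

# Central-difference gradient of a 3D array, per mm (one-sided at borders).
gradient3d <- function(a) {
  sp <- spacing_of(a)
  d <- dim(a)
  shift <- function(off, dim) {
    idx <- lapply(d, seq_len)
    idx[[dim]] <- pmin(pmax(seq_len(d[dim]) + off, 1L), d[dim])
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  list(
    x = (shift(1L, 1L) - shift(-1L, 1L)) / (2 * sp[1]),
    y = (shift(1L, 2L) - shift(-1L, 2L)) / (2 * sp[2]),
    z = (shift(1L, 3L) - shift(-1L, 3L)) / (2 * sp[3])
  )
}

# Bilinear rotation of a 2D matrix about its centre; zero fill outside.
rotate2d <- function(m, theta) {
  d <- dim(m)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  # pull-back: sample source at R(-theta) (x - c) + c
  dx <- g$i - cx; dy <- g$j - cy
  si <- cos(theta) * dx + sin(theta) * dy + cx
  sj <- -sin(theta) * dx + cos(theta) * dy + cy
  inb <- si >= 1 & si <= d[1] & sj >= 1 & sj <= d[2]
  i0 <- pmin(pmax(floor(si), 1L), d[1] - 1L); fi <- si - i0
  j0 <- pmin(pmax(floor(sj), 1L), d[2] - 1L); fj <- sj - j0
  base <- i0 + (j0 - 1) * d[1]
  v <- (1 - fj) * ((1 - fi) * m[base] + fi * m[base + 1]) +
    fj * ((1 - fi) * m[base + d[1]] + fi * m[base + d[1] + 1])
  v[!inb] <- 0
  matrix(v, d[1], d[2])
}
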