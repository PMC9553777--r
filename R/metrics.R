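#' Subject metadata for SUV normalization
#'
#' @param dose_MBq injected dose.
#' @param delay_min injection-to-scan delay, minutes.
#' @param weight_kg body weight.
#' @param half_life_min isotope half-life (default 109.77 for 18F).
#' @export
subject_meta <- function(dose_MBq = 305, delay_min = 90, weight_kg = 91,
                         half_life_min = 109.77) {
  if (!(dose_MBq > 0) || !(weight_kg > 0)) stop("dose and weight must be positive")
  stopifnot(delay_min >= 0, half_life_min > 0)
  structure(list(dose_MBq = dose_MBq, delay_min = delay_min,
                 weight_kg = weight_kg, half_life_min = half_life_min),
            class = "subject_meta")
}

#' Standardized uptake value image
#'
#' `SUV = C * W / D_corr` with activity concentration `C` in kBq/mL, body
#' weight `W` in g and the injected dose decay-corrected to scan start,
#' `D_corr = D * 2^(-delay / half_life)`, in kBq. Result in g/mL.
#'
#' @param activity_kBq_mL activity image (kBq/mL).
#' @param meta `subject_meta`.
#' @export
compute_suv <- function(activity_kBq_mL, meta) {
  stopifnot(inherits(meta, "subject_meta"))
  d_corr <- meta$dose_MBq * 1000 * 2^(-meta$delay_min / meta$half_life_min)
  activity_kBq_mL * (meta$weight_kg * 1000) / d_corr
}

# Inverse: activity concentration (kBq/mL) from an SUV image.
suv_to_activity <- function(suv, meta) {
  d_corr <- meta$dose_MBq * 1000 * 2^(-meta$delay_min / meta$half_life_min)
  suv * d_corr / (meta$weight_kg * 1000)
}

#' VOI statistics
#'
#' Mean and sample SD of the SUV inside a mask, plus the VOI volume from
#' voxel count times voxel volume.
#'
#' @param suv SUV volume.
#' @param mask 0/1 volume of the same shape.
#' @param label region label carried into the result.
#' @return `voi_stats`: list with `mean`, `sd`, `volume_cm3`, `n`, `label`.
#' @export
voi_statistics <- function(suv, mask, label = "region") {
  stopifnot(all(dim(suv) == dim(mask)))
  sel <- mask > 0.5
  n <- sum(sel)
  if (n < 1L) stop("empty mask")
  vals <- suv[sel]
  sp <- spacing_of(suv)
  structure(list(mean = mean(vals),
                 sd = if (n > 1L) stats::sd(vals) else 0,
                 volume_cm3 = n * prod(sp) / 1000,
                 n = n, label = label),
            class = "voi_stats")
}

#' Image quality metrics from myocardial and blood-pool VOI statistics
#'
#' Contrast ratio `CR = SUVmean_myo / SUVmean_blood`; signal-to-noise ratio
#' `SNR = SUVmean_myo / SUVsd_blood`; coefficient of variation
#' `CV = SUVsd_myo / SUVmean_myo` (reported in percent); contrast-to-noise
#' ratio `CNR = (SUVmean_myo - SUVmean_blood) / SUVsd_blood`. A zero
#' denominator yields `NA` with a warning rather than an error.
#'
#' @param myo,blood `voi_stats` for the myocardium and blood pool.
#' @return list with `CR`, `SNR`, `CV_pct`, `CNR`.
#' @export
image_quality_metrics <- function(myo, blood) {
  safe_div <- function(num, den, name) {
    if (!is.finite(den) || den == 0) {
      warning(sprintf("undefined metric %s: zero denominator", name))
      return(NA_real_)
    }
    num / den
  }
  list(CR = safe_div(myo$mean, blood$mean, "CR"),
       SNR = safe_div(myo$mean, blood$sd, "SNR"),
       CV_pct = 100 * safe_div(myo$sd, myo$mean, "CV"),
       CNR = safe_div(myo$mean - blood$mean, blood$sd, "CNR"))
}

#' Myocardial wall thickness from an uptake profile
#'
#' Samples the image along a line (trilinear interpolation at `step_mm`),
#' takes the baseline as the larger of the two profile end values, the
#' half-maximum as `baseline + 0.5 * (peak - baseline)`, and returns the
#' distance between the linearly interpolated half-maximum crossings
#' bracketing the peak. The line must traverse exactly one wall segment with
#' the peak strictly above both ends.
#'
#' @param suv SUV volume.
#' @param p0_mm,p1_mm profile endpoints in world mm (centre of voxel
#'   `[1,1,1]` is the origin).
#' @param step_mm sampling step along the line.
#' @return FWHM in mm; the sampled profile is attached as attribute
#'   `profile`.
#' @export
myocardial_wall_thickness <- function(suv, p0_mm, p1_mm, step_mm = 0.5) {
  sp <- spacing_of(suv)
  len <- sqrt(sum((p1_mm - p0_mm)^2))
  stopifnot(len > 0, step_mm > 0)
  s <- seq(0, len, by = step_mm)
  dir <- (p1_mm - p0_mm) / len
  px <- p0_mm[1] + s * dir[1]; py <- p0_mm[2] + s * dir[2]; pz <- p0_mm[3] + s * dir[3]
  v <- trilinear_at(suv, px / sp[1] + 1, py / sp[2] + 1, pz / sp[3] + 1)
  np <- length(v)
  pk <- which.max(v)
  baseline <- max(v[1], v[np])
  if (pk %in% c(1L, np) || v[pk] <= baseline) {
    stop("profile peak not strictly above both ends; does the line cross the wall?")
  }
  half <- baseline + 0.5 * (v[pk] - baseline)
  cross_left <- NA_real_
  for (i in seq(pk - 1L, 1L)) {
    if (v[i] < half) {
      cross_left <- s[i] + (half - v[i]) / (v[i + 1] - v[i]) * step_mm
      break
    }
  }
  cross_right <- NA_real_
  for (i in seq(pk + 1L, np)) {
    if (v[i] < half) {
      cross_right <- s[i] - (half - v[i]) / (v[i - 1] - v[i]) * step_mm
      break
    }
  }
  if (!is.finite(cross_left) || !is.finite(cross_right)) {
    stop("profile does not fall below half maximum on both sides of the peak")
  }
  out <- cross_right - cross_left
  attr(out, "profile") <- data.frame(s_mm = s, value = v)
  out
}

#' Morphological erosion / closing of a binary mask
#'
#' 6-neighbourhood structuring element, applied `iterations` times. Closing
#' (dilate then erode) is the smoothing the study protocol applies to
#' imperfect manually drawn VOIs; the phantom's exact masks do not need it.
#'
#' @param mask 0/1 volume.
#' @param iterations passes of the structuring element.
#' @export
erode_mask <- function(mask, iterations = 1L) {
  m <- unclass(mask) > 0.5
  d <- dim(m)
  shift <- function(a, off, dim) {
    idx <- lapply(d, seq_len)
    src <- seq_len(d[dim]) + off
    pad <- src < 1L | src > d[dim]
    idx[[dim]] <- pmin(pmax(src, 1L), d[dim])
    out <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
    slc <- lapply(d, seq_len); slc[[dim]] <- which(pad)
    if (any(pad)) out <- do.call(`[<-`, c(list(out), slc, list(value = FALSE)))
    out
  }
  for (it in seq_len(iterations)) {
    acc <- m
    for (dd in 1:3) acc <- acc & shift(m, 1L, dd) & shift(m, -1L, dd)
    m <- acc
  }
  out <- array(as.numeric(m), d)
  attributes(out) <- attributes(unclass(mask))
  out
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, iterations = 1L) {
  1 - erode_mask(as_volume(1 - unclass(mask), spacing_of(mask)), iterations)
}

#' @rdname erode_mask
#' @export
close_mask <- function(mask, iterations = 1L) {
  erode_mask(dilate_mask(mask, iterations), iterations)
}

#' Evaluate the four method variants
#'
#' Computes SUV statistics, the four quality ratios and the wall-thickness
#' FWHM for each supplied image (typically NG, DG, MoCo, MoCo-4D) on a common
#' grid with shared masks.
#'
#' @param images named list of activity volumes (kBq/mL).
#' @param mask_myo,mask_blood 0/1 volumes.
#' @param meta `subject_meta`.
#' @param profile list with `p0_mm`, `p1_mm` (and optional `step_mm`) for the
#'   wall-thickness profile.
#' @return `quality_report`: data.frame with one row per method and columns
#'   `suv_myo`, `suv_myo_sd`, `suv_blood`, `suv_blood_sd`, `CR`, `SNR`,
#'   `CV_pct`, `CNR`, `MWT_mm`.
#' @export
evaluate_methods <- function(images, mask_myo, mask_blood, meta, profile) {
  stopifnot(length(images) >= 1L, !is.null(names(images)))
  step <- profile$step_mm %||% 0.5
  rows <- lapply(names(images), function(nm) {
    img <- images[[nm]]
    stopifnot(all(dim(img) == dim(mask_myo)))
    suv <- compute_suv(img, meta)
    myo <- voi_statistics(suv, mask_myo, "myocardium")
    blood <- voi_statistics(suv, mask_blood, "blood_pool")
    q <- image_quality_metrics(myo, blood)
    mwt <- myocardial_wall_thickness(suv, profile$p0_mm, profile$p1_mm, step)
    data.frame(method = nm, suv_myo = myo$mean, suv_myo_sd = myo$sd,
               suv_blood = blood$mean, suv_blood_sd = blood$sd,
               CR = q$CR, SNR = q$SNR, CV_pct = q$CV_pct, CNR = q$CNR,
               MWT_mm = as.numeric(mwt))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("quality_report", class(out))
  out
}

#' @export
print.quality_report <- function(x, ...) {
  cat("Image quality metrics (CR, SNR, CV %, CNR, MWT mm):\n")
  print.data.frame(cbind(method = x$method,
                         round(x[, c("CR", "SNR", "CV_pct", "CNR", "MWT_mm")], 2)),
                   row.names = FALSE)
  invisible(x)
}

#' Serialize a quality report to JSON (round-trip lossless)
#' @param report `quality_report`; `path` file path.
#' @param path output path.
#' @export
write_quality_report_json <- function(report, path) {
  jsonlite::write_json(as.data.frame(unclass(report)), path, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_quality_report_json
#' @export
read_quality_report_json <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(out) <- c("quality_report", class(out))
  out
}
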