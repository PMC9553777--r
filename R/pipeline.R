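#' Default end-to-end pipeline configuration
#'
#' A plain nested list (YAML round-trippable) of every tunable in the
#' pipeline, with the clinical-protocol defaults: 24-minute acquisition,
#' 5 x 5 dual gates with the 50/120/420/550/1500 ms cardiac division,
#' 2 it / 24 subsets / 6 mm filter reconstruction settings, and the
#' 10/10/30-iteration three-level registration schedule.
#'
#' @param seed master seed; per-stage child seeds are derived from it.
#' @param shape phantom grid (shrink for quick runs; all mm-scale physics is
#'   unchanged).
#' @param duration_s acquisition duration.
#' @param counts_budget expected total counts; `NULL` = calibrate from
#'   clinical DG noise (see [calibrate_counts_budget()]).
#' @export
default_pipeline_config <- function(seed = 1L, shape = c(128L, 128L, 48L),
                                    duration_s = 1440, counts_budget = NULL) {
  list(
    seed = as.integer(seed),
    phantom = list(shape = as.integer(shape), spacing_mm = 2.73),
    trace = list(duration = duration_s, period = 5, period_jitter = 0.05,
                 amplitude = 10, amplitude_jitter = 0.1,
                 invalid_cycle_rate = 0.14, waveform = "sinusoid", fs = 25),
    triggers = list(mean_hr = 61.95, sd_hr = 11.71),
    gating = list(division_ms = c(50, 120, 420, 550, 1500), n_bins = 5L),
    recon = list(postfilter_fwhm_mm = 6, use_projector = FALSE,
                 iterations = 2L, subsets = 24L, n_angles = 96L,
                 ctac_emulation = TRUE, sens_angles = 12L),
    registration = list(factors = c(4L, 2L, 1L), iterations = c(10L, 10L, 30L),
                        sigma_update_vox = 3, sigma_field_vox = 0,
                        presmooth_mm = 1, alpha = 1, kappa = 0.25,
                        force = "demons"),
    metrics = list(dose_MBq = 305, delay_min = 90, weight_kg = 91,
                   blood_erode = 1L, profile_step_mm = 0.5),
    counts_budget = counts_budget
  )
}

#' Write / read a pipeline configuration as YAML
#' @param config nested list as from [default_pipeline_config()].
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) yaml::read_yaml(path)

#' Run the full dual-gated motion-correction pipeline
#'
#' Phantom signals -> dual-gating -> per-bin images (+ attenuation handling)
#' -> registration -> metrics. Produces the four method variants: NG
#' (non-gated, CINE-averaged mu), DG (bin 25, CINE mu), MoCo (corrected bins
#' 21-25, CINE mu), MoCo-4D (corrected bins 21-25, phase-matched mu). By
#' default attenuation enters through the image-domain sensitivity emulation;
#' set `config$recon$use_projector = TRUE` for slice-wise sinogram + OSEM
#' reconstruction. Fully reproducible for a fixed seed.
#'
#' @param config nested list, see [default_pipeline_config()].
#' @param out_dir optional directory; all artifacts (NIfTI volumes, CSVs,
#'   JSON reports, the config and a structured log) are written there.
#' @return `dualgate_result`: list with `images` (NG/DG/MoCo/MoCo-4D, kBq/mL),
#'   `quality` (a `quality_report`), `fractions`, `moco`, `moco4d`, `study`,
#'   `seeds`, `log`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message("[dualgate] ", msg)
  }
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L, 3L))
  say("seed %d -> stage seeds trace=%d triggers=%d noise=%d",
      config$seed, seeds[1], seeds[2], seeds[3])

  spec <- do.call(phantom_spec, config$phantom)
  trace <- do.call(generate_respiratory_trace,
                   c(config$trace, list(seed = seeds[1])))
  duration <- max(trace$time_s)
  triggers <- do.call(generate_cardiac_triggers,
                      c(list(duration = duration), config$triggers,
                        list(seed = seeds[2])))
  say("phantom %s, trace %.0f s (%d samples), %d triggers",
      paste(spec$shape, collapse = "x"), duration, nrow(trace), length(triggers))

  study <- simulate_gated_study(
    spec, trace, triggers, counts_budget = config$counts_budget,
    division_ms = config$gating$division_ms, n_bins = config$gating$n_bins,
    seed = seeds[3])
  say("dual-gated study: DG %.2f%%, MoCo %.2f%%, budget %.3g counts",
      100 * study$fractions$dg_fraction, 100 * study$fractions$moco_fraction,
      study$counts_budget)

  fwhm <- config$recon$postfilter_fwhm_mm
  pf <- function(img) gaussian_postfilter(img, fwhm)
  n_bins <- config$gating$n_bins
  n_total <- length(study$bins)

  # attenuation handling: sensitivity-ratio emulation (default) or full recon
  ratio_phase <- replicate(n_bins, NULL, simplify = FALSE)
  ratio_ng <- NULL
  if (isTRUE(config$recon$ctac_emulation) && !isTRUE(config$recon$use_projector)) {
    na <- config$recon$sens_angles
    sens_cine <- attenuation_sensitivity(study$mu_cine, na)
    resp_fracs <- vapply(seq_len(n_bins), function(r) {
      sum(study$fractions$bin_fractions[seq(r, n_total, by = n_bins)])
    }, numeric(1))
    w <- if (sum(resp_fracs) > 0) resp_fracs / sum(resp_fracs) else
      rep(1 / n_bins, n_bins)
    sens_avg <- array(0, spec$shape)
    for (r in seq_len(n_bins)) {
      s_r <- attenuation_sensitivity(study$mu_phases[[r]], na)
      ratio_phase[[r]] <- as_volume(pmin(pmax(s_r / sens_cine, 0.5), 2), spec$spacing)
      sens_avg <- sens_avg + w[r] * s_r
    }
    ratio_ng <- as_volume(pmin(pmax(sens_avg / sens_cine, 0.5), 2), spec$spacing)
    say("CTAC emulation: sensitivity ratios over %d angles", na)
  }
  apply_ratio <- function(img, ratio) {
    if (is.null(ratio)) img else as_volume(unclass(img) * unclass(ratio),
                                           spacing_of(img))
  }

  schedule <- do.call(registration_schedule, config$registration)
  if (isTRUE(config$recon$use_projector)) {
    rc <- recon_config(config$recon$iterations, config$recon$subsets,
                       fwhm, n = spec$shape[1], n_angles = config$recon$n_angles)
    say("projector path: OSEM %d it x %d subsets, %d angles",
        rc$iterations, rc$subsets, rc$n_angles)
    ng_img <- pf(recon_study_volume(study, bin = NULL, mu_used = study$mu_cine,
                                    config = rc, seed = seeds[3] + 101))
    dg_img <- pf(recon_study_volume(study, bin = 25L, mu_used = study$mu_cine,
                                    config = rc, seed = seeds[3] + 102))
    cine_imgs <- lapply(1:5, function(r) {
      pf(recon_study_volume(study, bin = 20L + r, mu_used = study$mu_cine,
                            config = rc, seed = seeds[3] + 110 + r))
    })
    gated_imgs <- lapply(1:5, function(r) {
      pf(recon_study_volume(study, bin = 20L + r,
                            mu_used = study$mu_phases[[r]],
                            config = rc, seed = seeds[3] + 110 + r))
    })
  } else {
    ng_img <- pf(apply_ratio(study$ng$noisy, ratio_ng))
    dg_img <- pf(apply_ratio(study$bins[[n_total]]$noisy, ratio_phase[[n_bins]]))
    cine_imgs <- lapply(seq_len(n_bins), function(r) {
      pf(apply_ratio(study$bins[[n_total - n_bins + r]]$noisy, ratio_phase[[r]]))
    })
    gated_imgs <- lapply(seq_len(n_bins), function(r) {
      pf(study$bins[[n_total - n_bins + r]]$noisy)
    })
  }

  say("registering diastolic gates (CINE-mu set)")
  moco <- motion_correct_diastole(study, schedule, images = cine_imgs)
  say("registering diastolic gates (4D-mu set)")
  moco4d <- motion_correct_diastole(study, schedule, images = gated_imgs)

  ref <- render_phantom_frame(spec, 0, 0)
  mask_myo <- ref$mask_myo
  mask_blood <- erode_mask(ref$mask_blood, config$metrics$blood_erode)
  meta <- subject_meta(config$metrics$dose_MBq, config$metrics$delay_min,
                       config$metrics$weight_kg)
  centre <- (spec$shape - 1) / 2 * spec$spacing
  profile <- list(p0_mm = centre,
                  p1_mm = centre + c(2 * spec$r_epi, 0, 0),
                  step_mm = config$metrics$profile_step_mm)

  # study images are in SUV-equivalent units; express them as activity
  # concentration so the metrics stage exercises the SUV normalization
  to_act <- function(img) suv_to_activity(img, meta)
  images <- list(NG = to_act(ng_img), DG = to_act(dg_img),
                 MoCo = to_act(moco$image), `MoCo-4D` = to_act(moco4d$image))
  quality <- evaluate_methods(images, mask_myo, mask_blood, meta, profile)
  say("quality report computed; MoCo data fraction %.2f%%", 100 * moco$fraction)

  result <- structure(list(images = images, quality = quality,
                           fractions = study$fractions, moco = moco,
                           moco4d = moco4d, study = study, seeds = seeds,
                           config = config, log = log),
                      class = "dualgate_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.dualgate_result <- function(x, ...) {
  cat("<dualgate_result>\n")
  print(x$quality)
  print(x$fractions)
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#' @param result `dualgate_result`; `out_dir` target directory.
#' @param out_dir target directory (created if missing).
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$images)) {
    write_nifti(result$images[[nm]],
                file.path(out_dir, paste0(gsub("[^A-Za-z0-9]", "_", nm), ".nii")))
  }
  ref <- render_phantom_frame(result$study$spec, 0, 0)
  write_nifti(ref$mask_myo, file.path(out_dir, "mask_myo.nii"), "uint8")
  write_nifti(ref$mask_blood, file.path(out_dir, "mask_blood.nii"), "uint8")
  write_nifti(result$study$mu_cine, file.path(out_dir, "mu_cine.nii"))
  write_assignment_csv(result$study$assignment,
                       file.path(out_dir, "assignment.csv"))
  write_report_json(result$fractions[c("bin_fractions", "rejected_fraction",
                                       "invalid_cycle_loss", "dg_fraction",
                                       "moco_fraction")],
                    file.path(out_dir, "data_fractions.json"))
  write_quality_report_json(result$quality, file.path(out_dir, "quality.json"))
  write_pipeline_config(result$config, file.path(out_dir, "config.yaml"))
  writeLines(result$log, file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}

#' Slice-wise sinogram + OSEM reconstruction of a study image
#'
#' The opt-in projector path: forward-projects each slice of the bin's
#' noise-free mean with the true (per-bin CINE-averaged) attenuation, adds
#' Poisson noise at the bin's count share, and reconstructs with the supplied
#' correction mu-map. `bin = NULL` reconstructs the non-gated image.
#'
#' @param study `dual_gate_study`.
#' @param bin dual-bin number, or `NULL` for non-gated.
#' @param mu_used mu volume used for attenuation correction.
#' @param config `recon_config`.
#' @param seed noise seed; `noise = FALSE` for a noise-free reconstruction.
#' @param noise logical.
#' @export
recon_study_volume <- function(study, bin, mu_used, config, seed = NULL,
                               noise = TRUE) {
  spec <- study$spec
  src <- if (is.null(bin)) study$ng$mean else study$bins[[bin]]$mean
  fraction <- if (is.null(bin)) 1 else study$bins[[bin]]$fraction
  # the data really were attenuated by the bin's own respiratory phase;
  # the non-gated acquisition by the time-averaged (CINE) map
  n_bins <- length(study$mu_phases)
  mu_true <- if (is.null(bin)) study$mu_cine else
    study$mu_phases[[(bin - 1L) %% n_bins + 1L]]
  geom <- recon_geometry(spec$shape[1], spec$spacing[1], config$n_angles)
  d <- spec$shape
  out <- array(0, d)
  tot <- sum(src)
  budget <- study$counts_budget * fraction
  with_seed(seed, {
    for (k in seq_len(d[3])) {
      act <- src[, , k]
      if (sum(act) <= 0) next
      sino <- forward_project_attenuated(act, mu_true[, , k], geom)
      if (noise && budget > 0) {
        scale <- budget * (sum(act) / tot) / max(sum(sino), 1e-12)
        counts <- matrix(stats::rpois(length(sino), sino * scale),
                         nrow(sino), ncol(sino))
        sino_n <- counts / scale
        attributes(sino_n) <- attributes(sino)
        sino <- sino_n
      }
      out[, , k] <- osem_reconstruct(sino, mu_used[, , k], config)
    }
  })
  as_volume(out, spec$spacing)
}
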