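# dualgate

Dual-gated cardiac PET simulation, gating, and end-diastolic respiratory
motion correction, with image-quality metrics — an R package for researchers
developing or validating motion-management pipelines for cardiac PET/CT.

Respiratory and cardiac motion blur cardiac PET images. Dual-gating bins the
acquisition by respiratory amplitude and ECG phase into 5 × 5 = 25 gates, so
each gate is nearly motion-frozen but keeps only a few percent of the counts.
This package implements the clinically simple remedy: register the five
diastolic respiratory gates (bins 21–25) non-rigidly to the end-expiratory,
end-diastolic reference gate (bin 25) and average them — a motion-corrected
(MoCo) image using ~4× the data of the best single gate — with attenuation
handled either by a breathing-averaged CT surrogate (CINE) or by
phase-matched maps (MoCo-4D).

Everything runs on a synthetic cardiac-torso phantom with known motion,
masks, and Poisson counting statistics, so each stage is testable without
patient data:

- **phantom** — quasi-periodic respiratory traces (with invalid cycles), ECG
  R-peak triggers (truncated-normal RR), a 4D activity/μ phantom with
  ground-truth displacement fields, and a dual-gated study simulator.
- **gating** — amplitude thresholds (mean + SD of cycle maxima / mean of
  minima), 5 equidistant amplitude bins, fixed-time cardiac gates at
  50/120/420/550/1500 ms from the R-peak, dual-bin bookkeeping
  (`b = (c−1)·5 + r`, bin 25 = end-diastolic end-expiratory), dwell-fraction
  reports.
- **recon** — 2D attenuated parallel-beam projector (sparse system matrix),
  OSEM (2 it × 24 subsets), CINE-averaged vs gated μ-maps, 6 mm Gaussian
  post-filter, and an image-domain attenuation-sensitivity emulation for the
  fast default path.
- **registration** — multiresolution demons-type non-rigid registration
  (3 levels, 10/10/30 iterations), deformation fields in mm, diastolic
  motion correction with dwell-weighted combination.
- **metrics** — SUV (decay-corrected dose per body weight), VOI statistics,
  CR / SNR / CV / CNR, and myocardial wall thickness as the FWHM of an
  uptake profile.
- **cli_io** — YAML configs, CSV/NIfTI/JSON readers and writers, a seeded
  end-to-end pipeline, and a CLI (`inst/cli/dualgate`) with `simulate`,
  `gate`, `recon`, `moco`, `metrics`, `run-all`.

Coordinates: world mm, RAS, voxel `[1,1,1]` centre at the origin; volumes are
3D arrays with a `spacing` attribute, written as NIfTI-1.

## Worked example

```r
library(dualgate)
cfg <- default_pipeline_config(seed = 7, shape = c(64L, 64L, 32L))
res <- run_pipeline(cfg)       # ~3 min on one core at this desk scale
print(res$quality)
```

```
Image quality metrics (CR, SNR, CV %, CNR, MWT mm):
  method   CR   SNR CV_pct  CNR MWT_mm
      NG 1.35  5.67  25.44 1.47  10.40
      DG 2.00 13.05  15.53 6.54  10.50
    MoCo 1.97 14.89  14.62 7.34   9.79
 MoCo-4D 1.97 15.46  14.73 7.63   9.79
```

Reading the table: the non-gated image (NG) averages over all motion, so its
contrast ratio (CR) collapses toward 1 and its wall thickness (MWT) is
inflated; the single end-diastolic end-expiratory gate (DG) restores contrast
but is the noisiest (lowest SNR of the gated rows); motion correction (MoCo)
combines ~4× more data at the same motion-frozen geometry, raising SNR and
CNR above DG and giving the thinnest wall; phase-matched attenuation
(MoCo-4D) adds a further SNR/CNR increment over CINE-corrected MoCo. Data
preservation in the same run: DG 9.9% of the acquisition, MoCo 31.1%
(`res$fractions`, `res$moco$fraction`).

The full-size default (`default_pipeline_config(seed = 1)`, 128 × 128 × 48)
has the same interface; the desk-scale grid above only shrinks the field of
view, not the mm-scale physics.

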