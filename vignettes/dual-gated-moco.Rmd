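---
title: "Dual-gated cardiac PET motion correction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-gated cardiac PET motion correction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Respiratory and cardiac motion blur cardiac PET images, reducing contrast and
quantitative accuracy. Dual-gating bins list-mode data simultaneously by
respiratory amplitude and cardiac (ECG) phase — here 5 x 5 = 25 bins — so
that each bin is nearly motion-frozen, at the cost of discarding most of the
counts. The remedy implemented by this package is end-diastolic respiratory
motion correction: all five diastolic respiratory gates (bins 21–25) are
registered non-rigidly to the end-expiratory, end-diastolic gate (bin 25) and
averaged, recovering roughly four times the data of the single best bin while
keeping its motion-frozen geometry. Attenuation correction can use either a
breathing-averaged CT surrogate (CINE) or a phase-matched (4D) surrogate; the
package produces all four method variants (NG, DG, MoCo, MoCo-4D) from one
seeded configuration and quantifies them.

`dualgate` is a simulation-first implementation: every stage runs on a
synthetic cardiac-torso phantom with known motion, masks and counting
statistics, so each algorithmic claim is testable without patient data. A
real-data path exists through the same interfaces (NIfTI volumes, trace and
trigger CSVs).

## Gating model

**Respiratory (amplitude) gating.** Cycles are delimited at end-expiratory
minima of the surrogate signal. The upper threshold is the mean plus one
sample standard deviation of the valid-cycle amplitude maxima; the lower
threshold is the mean of the valid-cycle minima; five equidistant amplitude
bins span the interval, bin 1 most inspired, bin 5 end-expiratory. Amplitudes
below the lower threshold are clipped into bin 5 — half of all cycle minima
necessarily fall below the mean of minima, and discarding them would halve
the end-expiratory data, contradicting the ~30% occupancy this binning is
designed to deliver. Amplitudes above the upper threshold are rejected, as
are samples in invalid cycles. For a pure sinusoid the bottom-bin occupancy
has the closed form arccos(0.6)/pi = 29.5% of the period; this is acceptance
target t2.

The device that produces the clinical surrogate flags "valid cycles" by an
unpublished internal rule. The package's stand-in, declared not inferred: a
cycle is valid when its period lies within [0.5, 2] times the median period
and its peak-to-trough range is at least 0.3 times the median range. Both
factors are configuration-exposed.

**Cardiac (fixed-time) gating.** Gates are fixed times from the previous
R-peak with division points 50, 120, 420, 550 and 1500 ms, half-open and
lower-closed. Elapsed times of at least 1500 ms are rejected rather than
folded into the diastolic gate, because 1500 ms is a printed division point;
cycles shorter than a division point simply leave later gates empty. At the
cohort's beta-blocked heart rate (~62 bpm) the diastolic gate holds ~35–45%
of each beat.

**Dual bins.** `b = (c - 1) * 5 + r`. This is the only layout in which
bin 25 is simultaneously end-diastolic and end-expiratory and bins 21–25 are
the diastolic set across respiration. Dwell fractions are computed over all
samples, so the 25 bin fractions plus the rejected fraction sum to one
exactly; the DG data-preservation figure is the bin-25 fraction and the MoCo
figure is the sum over bins 21–25.

## The phantom

A soft-tissue body ellipse with two lungs and a left-ventricular spherical
shell (endo/epi radii 25/35 mm at end-diastole, i.e. a 10 mm wall).
Activities are in SUV-equivalent g/mL: myocardium 2.15 and blood pool 0.86
(the non-gated medians of the emulated clinical cohort), soft tissue 0.4,
lung 0.15. Attenuation: 0.096 cm^-1 tissue, 0.03 cm^-1 lung. Respiration
translates the heart and lungs superior-inferiorly by up to 12 mm (a typical
diaphragmatic excursion); cardiac contraction scales the endocardial radius
by up to 25% at end-systole with half that contraction applied to the
epicardium, so the wall thickens in systole. The contraction profile is a
raised cosine of a normalized phase tied to the fixed-time gate scheme:
contraction runs between the 50 ms and 550 ms division points and peaks at
300 ms, so every sample in the diastolic gate is at rest geometry. The
ground-truth displacement field is the analytic composition of the radial
scaling and the translation, exactly invertible in the pure-translation case.

The breathing waveform defaults to a raised-cosine sinusoid, whose arcsine
dwell density reproduces the ~30% end-expiratory occupancy; a `cos4`
(sin^4) option gives more end-expiratory-weighted breathing. The subjects'
actual waveform shape is not recorded anywhere; the sinusoid is a modeling
choice, not a claim. Corrupted cycles (amplitude collapse to 15%, or a 2.6x
period outlier) are injected at a default per-cycle rate of 14%, mirroring
the reported mean invalid-cycle data loss (13.84%); period-outlier cycles
last longer, so the realized time-loss fraction runs somewhat above the
per-cycle rate.

**Counting statistics.** The acquisition's count total is not a stated
parameter, so it is calibrated once from clinical gated-bin noise: a DG image
with SNR ~ 20.3 at myocardial SUV 1.96 and blood SUV 0.82 implies a
post-filter blood-pool coefficient of variation of (1.96/20.3)/0.82 = 11.8%.
Given the 6 mm post-filter's white-noise suppression factor (computed exactly
from the discrete kernel) and the nominal 10.38% DG dwell, this fixes the
expected counts per blood-pool voxel and hence the budget
(`calibrate_counts_budget()`). Noise is Poisson in image space per bin, with
each bin's expected total equal to its dwell fraction times the budget; the
motion correction operates post-reconstruction, so reconstruction fidelity
is orthogonal to the default pipeline, and the projector/OSEM path is opt-in
(`recon$use_projector`).

What the generator does **not** emulate: scatter and randoms, perfusion
defects and low-uptake lesions, intra-bin residual motion, VOI-delineation
variability, and correlated (reconstruction-shaped) noise texture. A green
end-to-end test therefore establishes the internal consistency of gating,
registration and metrics on a known-truth world — not clinical performance.

## Reconstruction and attenuation handling

The projector is 2D parallel-beam, slice-wise, built as an explicit sparse
system matrix with Joseph-style bilinear sampling at half-pixel steps; PET
coincidence attenuation multiplies each ray by exp(-integral of mu over the
full chord). OSEM uses 2 iterations and 24 angle-interleaved subsets with a
uniform positive start, followed by a 6 mm Gaussian post-filter; with one
subset it reduces to MLEM exactly. Resolution recovery (PSF), scatter and
randoms are deliberately out of scope.

For the default image-domain pipeline, the quantitative effect of a
mismatched attenuation map is emulated to first order by the angular-mean
chord-attenuation sensitivity `s(x) = mean_theta exp(-integral mu)`: a bin
whose data were attenuated by the phase-true map but corrected with map `m`
is scaled by `s_true/s_m` (clamped to [0.5, 2]). CINE-corrected methods (NG,
DG, MoCo) acquire a small systematic bias near the lung–heart interface;
phase-matched correction (MoCo-4D) does not. This reproduces the direction
and magnitude (a few percent) of the CINE-vs-4D difference at a fraction of
the cost of per-bin OSEM; the full path remains available and is tested.
When CT and PET bin edges differ on real data, the gated map is chosen by
nearest bin.

## Registration

The force is the demons/optical-flow update
`alpha (F - M(u)) grad M(u) / (|grad M(u)|^2 + kappa (F - M(u))^2 / s^2 + eps)`
with `s` the mean voxel spacing at the current pyramid level and
`eps = (1e-6 * intensity scale / s)^2`, making the field exactly invariant
under global intensity rescaling. Three levels (downsampling 4/2/1) with
10/10/30 iterations, additive (non-diffeomorphic) field composition, and a
1 mm Gaussian pre-smoothing applied to **both** images — symmetric smoothing
makes identical inputs produce an exactly zero field. Updates are smoothed
with a Gaussian (fluid regularization), capped at one voxel per iteration
(trust region), and generate no force on the outermost voxel shell, where
one-sided gradients meet border-clamped samples and the residual is
unmatchable.

The source protocol regularizes updates with an unitless "sigma = .2" from a
closed vendor implementation. Read as 0.2 voxels this is effectively no
regularization, and two failures follow, both reproduced experimentally in
this codebase: the plain force is locally unstable (displacements at
unmatchable voxels grow without bound until the divergence guard aborts),
and — even when stabilized by elastic field smoothing — the recovered field
cannot propagate a rigid translation across the equatorial band of the LV
shell, where the aperture problem makes superior-inferior motion locally
unobservable and only tangential spreading of the update can carry it.
Elastic (whole-field) smoothing is the wrong tool, as it also erodes the
accumulated displacement bump each iteration. The package therefore defaults
to a fluid kernel of 3 voxels with `kappa = 0.25` and no elastic term, which
recovers 4–8 mm translations within half a voxel and a 15% radial
contraction at Dice >= 0.9; all constants are exposed in
`registration_schedule()`, and `force = "levelset"` drops the kappa term.

Motion correction registers bins 21–24 to bin 25 post-reconstruction (i.e.
after the 6 mm filter, which also conditions the Poisson noise for
registration) and combines the five gates by a dwell-fraction-weighted mean
(the protocol says only "combined"; weighting by dwell minimizes the
variance of the average, and an unweighted mean is available).

## Metrics

SUV = C * W / D with the dose decay-corrected to scan start (default 109.77
min half-life). VOI statistics use the sample SD everywhere, consistent with
the gating thresholds. The four ratios are CR = SUVmean_myo/SUVmean_blood,
SNR = SUVmean_myo/SUVsd_blood, CV = SUVsd_myo/SUVmean_myo (in %), and
CNR = (SUVmean_myo - SUVmean_blood)/SUVsd_blood; zero denominators flag the
metric as undefined rather than erroring. Wall thickness is the FWHM of a
linearly interpolated uptake profile across the antero-lateral wall at the
midventricular level; the baseline is the larger of the two profile end
values — blood-pool and background uptake are nonzero, so a zero baseline
would overstate the width; the convention is otherwise unstated upstream.
The profile is specified by explicit endpoints in the configuration (the
clinical placement is operator-defined); the pipeline default runs from the
LV centre radially outward through the wall.

Masks are the phantom's exact reference-state masks (blood pool eroded one
voxel to avoid rim partial-volume), shared by all four methods. Automatic
per-image segmentation is out of scope; a morphological-closing utility is
provided for imperfect real-data masks.

## Numerical choices

- Half-pixel ray sampling in the projector (disk-Radon agreement <= 2%
  away from the rim); ray ordering offset-major within angle; subset `i`
  takes angles `i, i + 24, ...` deterministically.
- Trilinear pull-back interpolation for warps, zero-filled outside the grid
  (border-clamped inside the registration loop only).
- Gaussian kernels are discrete, truncated at 3 sigma and renormalized;
  `fwhm = 0` is the identity.
- The master seed fans out to per-stage child seeds through one draw, so
  stages can be reproduced independently; every generator restores the
  caller's RNG state.
- Degenerate inputs: monotone traces (no detectable cycles), empty trigger
  lists, empty masks, all-zero sinograms and empty bins raise errors or
  logged warnings rather than propagating NaNs; a field exceeding one third
  of the field of view aborts registration with a diagnostic.

## Known limitations

- The CV of the non-gated image under fixed ground-truth masks is dominated
  by motion-blur heterogeneity at the myocardial rim, not by noise; the
  clinical observation that non-gated CV is the lowest of the four methods
  arises with per-image VOI delineation, which this package deliberately
  does not model. The gated-method CV ordering (DG > MoCo-4D > MoCo) is
  reproduced.
- 2D slice-wise geometry; no PSF, scatter, randoms, or time-of-flight.
- Additive field composition is not guaranteed diffeomorphic for large
  deformations.
- Desk-scale grids: the default 128 x 128 x 48 at 2.73 mm mirrors a clinical
  matrix scaled down; tests run on smaller fields of view with identical
  mm-scale physics.
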