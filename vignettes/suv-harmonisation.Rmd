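---
title: "Harmonising SUVmax across PET scanners with Gaussian resolution matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonising SUVmax across PET scanners with Gaussian resolution matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The standardised uptake value (SUV) of a lesion depends not only on the
tracer uptake but on the effective spatial resolution of the scanner and
reconstruction that produced the image. A small hot lesion imaged on a
modern time-of-flight system with resolution-recovery (RR) reconstruction
can easily report a SUVmax 20% higher than the same lesion imaged on an
older 2D BGO system. When SUVs from different devices are compared —
response assessment across a scanner replacement, multicentre trials,
scanner downtime — this resolution dependence becomes a systematic bias.

*Harmonisation* removes the bias by degrading the sharper system to a
common resolution target. The approach implemented here applies a single
3D Gaussian kernel to the images of a scanner/protocol; the kernel width
(FWHM, mm) is chosen so that the protocol's phantom recovery coefficients
fall inside a per-sphere acceptance window, either an accreditation-style
table (EARL) or a window transferred from a second scanner. The kernel is
cheap enough to apply on the fly, so reading happens on the original image
while the harmonised SUV is reported alongside — no second reconstruction
is needed.

## The measurement model

All quantities are derived from the NEMA IEC body phantom: six fillable
spheres (10, 13, 17, 22, 28, 37 mm) on a 114.4 mm pitch circle, filled at
45 kBq/ml over a 5 kBq/ml background (9:1). For a sphere of diameter $d$
the maximum-voxel recovery coefficient is

$$\mathrm{RC}_{\max}(d) = \frac{\max_{v \in \mathrm{VOI}(d)} I(v)}{A_{\mathrm{true}}},$$

the measured maximum within a search region (sphere radius plus a blur
margin, default 10 mm) divided by the true filled activity. RCmax is the
only recovery metric used: SUVmax is the clinical quantity being
harmonised, and a Gaussian kernel acts directly on image maxima. Mean-type
metrics (A50 isocontour RCmean, SUVpeak, MTV, TLG) are out of scope.

Acquisition is modelled phenomenologically rather than by iterative
reconstruction: the harmonisation mathematics depends only on the
*effective* resolution of the reconstructed image, which for this purpose
is well described by

1. an isotropic Gaussian blur of FWHM $\sqrt{\mathrm{PSF}^2 +
   \mathrm{postfilter}^2}$;
2. optionally, RR edge overshoot, emulated as an unsharp mask
   $I + \alpha\,(I - G_{\mathrm{PSF}} I)$ clipped at zero — this sharpens
   edges and overshoots at sphere boundaries, reproducing the
   characteristic RR behaviour of RCs rising above the acceptance window
   and even above 1;
3. trilinear resampling onto the scanner's reconstruction grid
   (matrix / slice thickness);
4. additive zero-mean Gaussian replicate noise with sd expressed as a
   fraction of the background level.

Sinogram/Poisson noise, time-of-flight, attenuation and scatter, the lung
insert, and respiratory motion are deliberately not modelled.

## The harmonisation kernel and its optimiser

`apply_gaussian()` interprets the kernel width as the FWHM of the 3D
Gaussian, $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$, isotropic in mm
(per-axis $\sigma$ in voxel units for anisotropic grids). The kernel is
sampled, truncated at $6\sigma$ and renormalised, and applied as a
separable convolution with replicate edge padding. A nonnegative kernel
that sums to one guarantees two properties the package treats as
invariants: smoothing can never increase any maximum (so harmonised
SUVmax is always $\le$ raw SUVmax), and a flat region is left exactly
unchanged. At the voxel sizes used here the sampled kernel also composes
to floating precision: two successive filters of FWHM $f$ and $g$ equal a
single filter of $\sqrt{f^2+g^2}$ to better than $10^{-6}$ relative.

`optimise_filter()` minimises

$$J(f) = \sum_{\text{spheres}} \left( \frac{\mathrm{dist}\big(\mathrm{RC}_f(d),\,[\ell_d, u_d]\big)}{\mathrm{nominal}_d} \right)^{\!2},$$

where the distance is zero inside the closed band and the distance to the
nearest violated limit outside. RCs at each candidate $f$ are measured by
filtering every replicate scan and averaging, mirroring the replicate-mean
protocol used in practice (three scans per scanner here). The search is
derivative-free: a bracketing pass at 0.5 mm, a 0.1 mm grid inside the
bracket, then bisection/golden-section refinement to 0.01 mm. Band
intervals are closed — a recovery coefficient exactly on a limit passes,
matching accreditation practice; violations are reported as signed
percentage deviations beyond the violated limit.

$J$ is flat at zero across the whole all-pass region, so a tie-break is
needed. The package returns the **smallest** all-pass FWHM: minimal
smoothing preserves lesion detectability while already harmonising, which
is the point of single-dataset harmonisation. One consequence is worth
understanding. For accreditation-width windows (10–25% relative), band
entry happens well before the resolution-matched width — the sharper
scanner only needs to be smoothed until its most sensitive sphere drops
into the window, not until its whole RC curve matches the reference
nominals. The closed-form identity ("a pure-Gaussian scanner of blur $a$
matches a reference of blur $b$ at $f = \sqrt{b^2 - a^2}$") is therefore
validated with *narrow* windows (±2% around the reference RCs), where band
entry and resolution matching coincide; with EARL-width windows the
returned filter is deliberately smaller. If resolution matching itself is
wanted, pass a tight band table built from the reference profile.

Cross-scanner harmonisation has no published acceptance window, so the
reference window's relative widths are borrowed
(`derive_cross_scanner_bands()`): the target scanner's mean RC becomes
the nominal, and the limits are scaled by the reference table's
lower/nominal and upper/nominal ratios. Relative window widths are
preserved exactly by construction.

The EARL-style band asset shipped in `inst/extdata/earl_rc_max_bands.yaml`
encodes the published standard-1 RCmax ranges with the interval midpoint
as nominal. It is an editable configuration file, not a normative claim:
compliance logic is tested against synthetic tables, and sites should
substitute their accreditation programme's current values.

## The synthetic study

Because no public phantom or patient images accompany this design, the
package carries a first-class synthetic-data module and the default
`study_config()` encodes the whole study:

* **Virtual scanners.** `A` — a modern 3D system, effective PSF 4.4 mm,
  5 mm Gaussian post-filter, 200×200 matrix over a 400 mm FOV (2 mm
  pixels), simulated with (`A_RR`) and without (`A_noRR`) resolution
  recovery; `B` — an older 2D system, PSF 6.5 mm, 5.14 mm post-filter,
  128×128 matrix. The PSF widths are model choices selected so that the
  derived filters land in the few-millimetre range typical of this kind of
  harmonisation; they are not measurements of any commercial device, and
  the derived filter values are not expected to equal any particular
  published table. Under this pure-Gaussian model the virtual scanner B
  is already EARL-compliant untouched (filter 0 mm): real 2D systems
  carry non-Gaussian resolution losses that the phenomenological model
  does not reproduce.
* **RR overshoot** defaults to an unsharp amount of 1.0, which inflates
  SUVmax by roughly 10–25% for 10–20 mm lesions — the order reported for
  PSF-modelling reconstructions. **Replicate noise** defaults to 5% of
  background.
* **Phantom protocol.** Three replicate scans per protocol; replicate-mean
  RCs; four harmonisation pairs (A_RR→EARL, A_noRR→EARL, B→EARL, A_RR→B).
* **Clinical cohorts.** Two independent 40-patient cohorts (head &
  neck 10, lung 10, oesophagus 5, colorectum 8, lymphoma 7), one per
  scanner, plus a 10-patient paired RR/no-RR subset (1/5/4) in which both
  reconstructions derive from the same truth patch and the same noise
  realisation. Lesions are spheres with log-normal diameters (median
  20 mm, sdlog 0.35) and log-normal uptake (median SUV 8, sdlog 0.45) on
  a background of SUV 1, chosen once so simulated SUVmax spans roughly
  2–25; the values are stated assumptions, since no lesion-size or SUV
  distribution is available to fit.
* **Statistics.** SUVmax distributions are Shapiro-Wilk tested and log10
  transformed when normality is rejected (gate alpha 0.05), then compared
  by one-way ANOVA: the five-arm design over the 80 patients (A_RR raw,
  A_RR→EARL, A_RR→B, B raw, B→EARL; df 4, 195) and the four-arm design
  over the paired subset (df 3, 36). RR dependence is quantified by ratio
  Bland-Altman (mean ratio, limits of agreement at mean ± 1.96 sd — the
  "2×SD about the mean" convention — outliers beyond ±2 sd, and the
  Pearson correlation of ratio against pair mean) and by straight-line
  fits of no-RR against RR SUVmax. The Wilcoxon signed-rank helper
  (exact for ≤25 untied pairs, zero differences dropped, all-zero p = 1)
  is provided for paired comparisons; note that applying a paired test to
  demographics of two independent cohorts, as sometimes appears in
  clinical tables, answers a different question than intended.

```{r study}
library(petharm)
cfg <- study_config(seed = 20200602)
report <- run_study(cfg)
report$filters
glance(report$clinical$anova_main)
glance(report$clinical$bland_altman$raw)
glance(report$clinical$bland_altman$harmonised)
write_study_report(report, "study-output")
```

## Numerical choices and degenerate inputs

* Voxel centres sit at `origin + (index + 0.5) * voxel_size`; world
  coordinates in mm throughout.
* Ground-truth spheres are rendered with volume-fraction partial-volume
  weighting, supersampling boundary voxels at 4 points per axis. An even
  factor avoids the degenerate centre-aligned subsample; the rendered
  sphere volume is within ~0.2% of analytic at 1–2 mm voxels for every
  alignment tested, and sphere-core and background voxels keep their
  exact values so the 9:1 contrast is exact.
* The kernel truncation radius is 6σ for `apply_gaussian()` (semigroup
  holds to 1e-6) and 4σ inside the optimiser, where only band distances
  are needed and the induced RC error is below 1e-4.
* Resampling clamps sampling positions at the volume edge (replicate
  continuation); acquisition noise scales with the median voxel value as
  the background estimate.
* Degenerate cases are errors, not silent results: overlapping or
  out-of-field spheres, non-positive activities, empty patches,
  zero-variance input to the normality gate, constant x in a line fit,
  zero denominators in ratio analysis. The all-zero-difference signed
  rank test returns p = 1 by documented convention.
* If no kernel width in the search range achieves compliance the
  optimiser returns the best-effort minimiser with a positive residual
  and `all_pass = FALSE` — downstream code can flag it, and
  `residual == 0` is exactly equivalent to full band compliance.

## What the tests do and do not show

The test suite validates the machinery against independent oracles:
analytic sphere volumes, the Gaussian semigroup and FWHM definition,
hand-computed ANOVA and Bland-Altman arithmetic, brute-force sign
enumeration for the exact Wilcoxon p, Monte-Carlo type-I error for the
ANOVA, and the resolution-matching closed form. The study-level checks
are run at the study's own sizes: the default 2 mm phantom grid, two
40-patient cohorts, and 100 repetitions of the 10-patient paired design
for the direction-of-effect property (harmonisation pulls the RR/no-RR
SUVmax ratio towards 1 and shrinks its spread).

Passing these tests shows that the pipeline is internally correct under
the stated acquisition model. It does not show that the model captures
any particular scanner: real reconstructions have spatially varying,
non-Gaussian PSFs, count-dependent correlated noise, and lesions are
neither spherical nor homogeneous. Filter values derived here transfer to
real equipment only in direction and rough magnitude; a site deriving a
clinical harmonisation kernel must measure its own phantom data, and real
volumes can be fed to the same functions via `read_volume()` (NIfTI) with
sphere centres supplied in the configuration.
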