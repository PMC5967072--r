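---
title: "Quantitative PET/CMR after myocardial infarction: models, generator design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative PET/CMR after myocardial infarction: models, generator design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cmrpet implements the quantitative chain used to compare three image
signals of post-infarction tissue state — native T1 (edema / free water),
extracellular volume fraction (ECV; interstitial expansion and cellular
damage) and ^18^F-FDG uptake (a mixture of inflammatory-cell and
post-ischemic myocyte metabolism) — within and across patients, and to
relate focal image maxima to systemic blood markers. This vignette records
the models, the assumptions behind them, the design of the synthetic
cohort generator, and every numerical choice a maintainer might want to
revisit.

## 1. MOLLI T1 fitting

Magnitude inversion-recovery series are modeled as
$$S(TI) = \lvert A - B\,e^{-TI/T_1^*}\rvert,\qquad
T_1 = T_1^*\,(B/A - 1),$$
the standard three-parameter Look-Locker formulation. The 3(3)3(3)6
acquisition scheme is interpreted in the usual notation — images per look
outside the parentheses, recovery beats inside — giving 3 + 3 + 6 = 12
images; the effective inversion time of image $k$ (0-based) of look $g$ is
$TI_g + k \cdot 60000/\mathrm{HR}$ ms. The base inversion delays of the
prototype sequence are not standardized, so they are configuration
(`molli_scheme(base_ti = …)`, default 120/200/280 ms).

**Polarity restoration.** Only magnitude data is assumed, so the sign of
the earliest samples is recovered by exhaustive search: for every
candidate count $k = 0 \dots n-1$ of earliest samples negated, a full
three-parameter fit is run and the candidate with minimal residual RMS
wins. Since $k = 0$ is always a candidate, restoration can never worsen
the no-flip fit.

**Fitting algorithm.** For fixed $T_1^*$ the model is linear in $(A, B)$,
so the fit is solved by variable projection: an exact linear solve per
candidate $T_1^*$, a coarse 64-point log-spaced grid over
$[\min(TI)/20,\ 3\max(TI)]$, and a 48-iteration golden-section refinement
on $\log T_1^*$ — per flip candidate, vectorized over all pixels of a map.
We chose this over Levenberg–Marquardt because it is deterministic, cannot
diverge, needs no convergence tolerance, costs $O(\text{grid} \times
\text{flips})$ linear solves that vectorize across a whole map, and
recovers noiseless curves to better than $10^{-6}$ relative error — a
guarantee an iterative optimizer cannot give per pixel. Fits with
$B/A \le 1$, non-finite parameters, or $T_1^*$ pinned at a search bound
are flagged `ok = FALSE` (never an exception on finite input) and dropped
from map masks with a logged count.

The 3(3)3(3)6 scheme's known sensitivity to heart-rate variation is *not*
corrected; the simulation exposes it (the TI schedule is built from the
patient's heart rate) exactly as the measurement would.

## 2. ECV mapping

$$\mathrm{ECV} = (1 - \mathrm{Hct})\;
\frac{1/T_{1,\text{myo}}^{\text{post}} - 1/T_{1,\text{myo}}^{\text{native}}}
     {1/T_{1,\text{blood}}^{\text{post}} - 1/T_{1,\text{blood}}^{\text{native}}}$$

assumes contrast equilibration between blood and interstitium (violated by
microvascular obstruction, which is why such patients are excluded from
this kind of analysis). A non-positive blood $\Delta R_1$ is an error; a
negative myocardial $\Delta R_1$ flags the pixel invalid. Blood T1 is the
median over a cavity ROI (robust to partial-volume pixels); the same
cavity ROI feeds the PET TBR normalization, since nothing in the source
material distinguishes the two. Hematocrit is accepted as a fraction;
values above 1 are auto-detected as percent and divided by 100 with a
warning (both conventions are common in clinical CSVs). ECV is stored as a
fraction and rendered as percent in all tables.

## 3. PET quantification

$\mathrm{SUV}_{\mathrm{LBM}} = \text{activity} / (\text{dose}_{\text{decay-corrected}} / \mathrm{LBM})$
with the dose corrected to scan start by $e^{-\ln 2\, t/T_{1/2}}$
($T_{1/2} = 109.77$ min for F-18). Scanner software rarely documents its
LBM formula; we default to James (male $1.10W - 128(W/H)^2$, female
$1.07W - 148(W/H)^2$) with Janmahasatian as a configuration switch. TBR is
tissue SUV over the cavity-ROI median SUV; it is scale-free, so it is
computed from biopsy summaries by dividing by the per-patient blood SUV.

## 4. Sector segmentation

Endo- and epicardial contours are matched by equal-angle resampling about
the cavity centroid (adequate for near-convex LV short-axis slices;
contours that are not star-shaped about the centroid are rejected as
self-intersecting). The centerline is the pointwise midpoint curve,
sampled at 704 equal angles — a multiple of both 16 and 32, so rotating
the reference angle by a whole sector permutes labels exactly on
rotationally symmetric geometry. Its **arc length** (an open question in
the source description; angular division is the configurable alternative)
is divided into `n_sectors` equal **half-open** bins `[start, end)`
counter-clockwise from the reference angle (default 0 = image +x axis; no
anatomical anchoring is attempted, mirroring the "no additional
morphological reference" convention). Every annulus pixel joins the bin of
its nearest centerline sample — transmural assignment, deliberately so:
cardiac motion and PET resolution make sub-transmural layers meaningless
in this setting. Samples landing numerically on a bin boundary are snapped
to it ($|u - \mathrm{round}(u)| < 10^{-9}$ bins) so the partition is
stable under reference-angle rotation.

Per-sector values are means of valid pixels; a sector with less than
`min_valid_frac = 0.5` of its pixels valid (or none) is excluded with a
reason, and an exclusion in one modality excludes the sector in all three,
keeping the co-localized frame. Exclusions are flagged, not raised.

## 5. Biopsy statistics

Per patient and signal, located independently for each signal (anchoring
to a reference modality would bias the cross-modality comparison):

- **maximum** = mean of the two highest non-excluded sector values, ties
  broken toward the lower sector id;
- **remote** = mean of the three sectors as distal as possible from the
  single highest sector: the diametric opposite
  `((argmax − 1 + n/2) mod n) + 1` and its two ring neighbours, excluded
  members replaced by the next-most-distal valid sector (ties toward the
  lower id). This codifies deterministically what was a manual "as distal
  as possible" choice;
- **argmax distance** between signals = circular distance
  `min(|i − j|, n − |i − j|)`.

## 6. Correlation layer

*Between-subject*: Pearson r over per-patient means, $df = k - 2$.
*Within-subject*: the repeated-measures (ANCOVA) correlation — Pearson r
of patient-mean-centered pairs pooled over sectors, $df = N - k - 1$ —
algebraically identical to the partial correlation of the dummy-variable
multiple regression `y ~ patient + x` (the test suite asserts equality to
1e-10 against that oracle). The df convention $N - k - 1$ is adopted
explicitly since source conventions vary. Note that within-subject r = 1
requires a *common* slope: per-patient affine relations with heterogeneous
slopes do not center onto one line, so heterogeneity shows up as r < 1 by
design. Patients with fewer than two sectors or zero within-patient
variance are dropped with a warning. Per-subject slopes are ordinary least
squares, flagged below three sectors. Marker correlations are simple
Pearson r with pairwise deletion of missing values (per-cell n reported;
fewer than three pairs gives NA). Two-sided p-values at the conventional
5% level, no multiple-testing correction by default — a `bonferroni`
switch exists for users who want one.

## 7. The synthetic cohort generator

The generator emulates the *statistical structure the analysis assumes*,
not cardiac anatomy:

- one short-axis slice per patient: a circular annulus (defaults: 95 px
  grid, endo/epi radii 16/26 px) with two cavity disks carrying blood-pool
  native/post T1 and blood activity;
- a raised-cosine severity wedge $s(\theta)$, peak 1 at the infarct
  center, zero outside the half-width, **constant transmurally** (the
  analysis is transmural, so transmural structure would be
  unidentifiable); ground-truth infarct size = wedge fraction of the
  annulus, `half_width/π`;
- pixel truths `remote + gain·s(θ)` for native T1, ECV and FDG — one
  severity field drives all three maps, so within-slice co-localization is
  perfect by construction; the post-contrast T1 map is obtained by
  inverting the ECV equation, making the true pixel ECV recomputable
  exactly from the stored T1 pairs and hematocrit;
- MOLLI magnitude series generated from the true T1 maps through the
  signal model and the patient's heart-rate-dependent TI schedule, with
  Gaussian noise on the magnitude (the Rician floor is negligible at the
  simulated SNR ≥ 20, and Gaussian noise keeps closed-form bias
  expectations for the fit tests); default `noise_sd = 2` on an A = 100
  scale is SNR 50. Map-level noise defaults (15 ms native T1, 8 ms post
  T1, 0.05 SUV at `noise_sd = 2`) scale proportionally with `noise_sd`, so
  `noise_sd = 0` is a fully noise-free phantom.

Cohort structure (defaults are the study conditions: n = 25, infarct size
17.3 ± 7.1 %LV, maximum/remote levels 57.0 ± 7.8 / 27.8 %ECV,
1432 ± 101 / 1163 ms native T1, 2.62 ± 0.53 / 0.71 SUV, marker scales CK
1806 ± 930, CK-MB 211 ± 124, troponin T 2.5 ± 1.7, leukocytes 12.8 ± 4.3,
monocytes 1.1 ± 0.4, 24% apical slices — 6 of 25, assigned
deterministically to evenly spread patient ids — 88% male, HR 62 ± 9):

- latent axes: infarct extent, central severity (coupled to extent,
  ρ = 0.5) and systemic inflammation; the **damage** axis is the
  standardized extent + severity sum;
- designed per-patient *sector-scale maxima*: the ECV maximum loads on the
  damage axis such that corr(max ECV, infarct size) equals its design
  value (0.59); the native-T1 maximum loads on inflammation (ρ = 0.8); the
  FDG maximum mixes damage and inflammation (loadings 0.4/0.4) plus
  independent noise;
- blood markers are lognormal with the reported means and SDs, linear in
  the latent z-scores on the log scale. Because the recovery target is the
  *raw-scale* Pearson correlation, the latent coupling is corrected
  analytically: for marker $e^{\mu + \sigma U}$,
  $\mathrm{corr}(Z, e^{\mu+\sigma U}) = \rho\,\sigma/\sqrt{e^{\sigma^2}-1}$,
  so $\rho = r_{\text{target}}\sqrt{e^{\sigma^2}-1}/\sigma$. Defaults:
  CK-MB↔max ECV 0.60, CK↔max ECV 0.40, monocytes↔max T1 0.60,
  leukocytes↔max T1 0.43, troponin T↔max T1 0.45 (troponin also relates
  weakly to FDG through the shared inflammation axis). All couplings are
  configuration, and zero is an honest null.

Three construction rules make the designed maxima be what the sector
analysis measures:

1. **Sector-attenuation calibration.** A sector average of a narrow
   raised-cosine wedge is strictly below its peak, by a patient-specific
   factor κ (the analytic angular integral of $s$ over the two best
   analysis bins) that depends on wedge width, position and the 16/32
   sector count. Left uncorrected, this shared factor correlates the three
   measured maxima even when the designed gains are independent, and
   dilutes designed marker couplings. The generator therefore sets the
   pixel gain to (designed elevation)/κ, so the noise-free biopsy maximum
   equals the designed maximum for every geometry.
2. **Minimum elevations.** A per-patient maximum below its own remote
   level is not constructible (the max of a profile cannot undercut its
   baseline, and reported max/remote separations never overlap within
   patient); designed elevations are floored at 80 ms / 0.06 ECV /
   0.4 SUV.
3. **Physical ceiling.** Peak pixel ECV is capped at 0.95 (the blood-pool
   limit is 1), and infarct size is floored at 6 %LV so the κ correction
   cannot demand an unphysical ECV peak on narrow apical wedges.

What the generator does **not** emulate — and hence what green tests do
*not* establish about real data: realistic LV anatomy and wall-thickness
variation, respiratory/cardiac motion and registration error (series are
registered by construction; the real processing chain included manual
motion correction), microvascular-obstruction cores, PET partial-volume
effects and resolution mismatch, Rician noise tails at low SNR,
arrhythmia within an acquisition, and any systematic inter-modality
misregistration. Results on real data depend on exactly these terms.

## 8. Problem sizes and reproducibility

The test suite runs the stochastic checks at 200 replicate cohorts of
n = 25 (one null ensemble with independent maxima and zero marker
couplings; one ensemble at the designed couplings), 1000 pixels for the
SNR-50 fit benchmark, 50 pixels against the brute-force grid-search
oracle, and a 256-px grid for the sector-area uniformity check — sizes
chosen so the full suite completes in a few minutes on one CPU while
keeping Monte-Carlo error well below the asserted margins. All randomness
descends from explicit integer seeds through a local-RNG helper, so
nothing leaks into or out of the global RNG state; the full pipeline is
byte-reproducible for a fixed config and seed. `scripts/acceptance.R`
recomputes the headline quantities from scratch at the default conditions
for any `--seed`.

## 9. Known limitations

- The sector-area uniformity of an ideal circular annulus holds at generic
  reference angles; with boundaries exactly along pixel rows the half-open
  tie convention assigns whole rows to one side (a measure-zero degeneracy
  of the discretized geometry).
- The equal-angle contour matching assumes star-shaped contours; strongly
  concave slices (aneurysm) would need arc-length-parameterized matching.
- The κ calibration uses the analysis' default reference angle (0); an
  analysis run at a rotated reference frame measures maxima attenuated by
  the (small) difference between the two κ values.
- Between-subject correlations of *per-subject means* in generated cohorts
  are near zero because remote levels are drawn independently across
  patients; the generator controls maxima couplings, not mean couplings.
- File mode expects pre-registered inputs; no registration is performed.
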