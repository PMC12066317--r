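---
title: "Mapping DBS outcomes: VTA models, sweet spots and fiber T-scores"
author: "dbsmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping DBS outcomes: VTA models, sweet spots and fiber T-scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Subthalamic deep brain stimulation (STN-DBS) improves motor symptoms in
Parkinson's disease and, depending on where within the nucleus the
stimulation acts, can also improve or worsen anxiety and depression.
`dbsmap` implements the group-level mapping machinery used to ask
*where* stimulation helps: estimate each patient's volume of tissue
activated (VTA), relate VTA locations and their structural connectivity
to changes in clinical scale scores (HAMA, HAMD, UPDRS-III, PDQ-39,
LEDD; the change convention is `pre - post`, so positive change means
improvement), and validate the resulting spatial models by
cross-validated outcome prediction.

Because patient imaging and scores are not distributable, the package
ships a synthetic cohort generator with *planted* ground truth, so every
analysis stage has a recoverable answer and the whole pipeline is
testable end to end.

# VTA model

The field around the active contact is a quasi-static homogeneous
point source:

$$|E|(r) = \frac{U\, r_c}{r^2},\qquad r \ge r_c,$$

with stimulation amplitude $U$ (volts) and contact radius $r_c$ (mm,
default 0.635); inside the contact the field is clamped to $U/r_c$.
The binary VTA is the set of voxels whose center field meets the
activation threshold $E_{th}$ (default 0.2 V/mm), which for this field
is a ball of radius $r^* = \sqrt{U r_c / E_{th}}$ — about 2.82 mm at
2.5 V. This is deliberately the simplest field model that preserves the
thresholding semantics all downstream stages depend on; finite-element
fields with heterogeneous conductivity, directional leads and
current-controlled stimulation are out of scope, and the field function
is isolated behind `field_magnitude()` so a richer model can be slotted
in. Pulse width and frequency are carried on the electrode record but
do not enter the field model. Absolute VTA volumes from this model are
not comparable with FEM-based volumes; only their relative geometry is
used. Only voltage-controlled monopolar stimulation is supported.

Conventions: the world frame is RAS mm (ventral = smaller z), voxel
indices are 0-based in the affine, and masks live on voxel centers.
Four-contact leads have 2 mm center-to-center spacing by default
(configurable; the hardware's true geometry is not published, so the
default is a conventional lead pitch).

# Sweet-spot mapping

For one outcome (HAMA change by default; improvement rates via
`measure = "improvement"`):

1. **N-image** — per-voxel count of covering patient VTAs (each
   patient's mask is the union of both hemispheres by default;
   per-hemisphere analysis via `hemisphere =`).
2. **Coverage filter** — voxels covered by fewer than
   `ceiling(0.2 * N)` VTAs are excluded ("less than 20% excluded" is
   implemented as *keep iff count ≥ ceil(0.2 N)*).
3. **Mean-effect map** — per kept voxel, the mean change score of
   covering patients.
4. **Voxel-wise test** — two-sided Wilcoxon signed-rank of those
   changes against zero. Zeros are dropped, absolute values are ranked
   with midranks; for n ≤ 25 the exact sign-flip null distribution is
   built by integer-count convolution over the doubled midranks (exact
   under ties too, and bit-identical to brute-force sign enumeration);
   beyond that, a normal approximation with tie-corrected variance and
   continuity correction. A voxel whose covering changes are all zero
   gets p = 1.
5. **FDR** — Benjamini–Hochberg over kept voxels; **sweet** voxels have
   q ≤ 0.05 and positive mean change, **sour** voxels q ≤ 0.05 and
   negative mean change.

Voxels sharing the same covering-patient set necessarily share the same
mean and p, so the implementation groups kept voxels by coverage
pattern and computes each pattern once — identical output, an order of
magnitude faster.

## Prediction and cross-validation

The out-of-sample prediction for a held-out patient is the mean of the
trained mean-effect map over the patient's VTA ∩ significant voxels,
falling back to VTA ∩ kept voxels when no significant voxel is covered,
and to 0 (flagged) when the VTA misses the kept mask. This estimator is
a design choice — the overlap principle (more sweet, less sour = more
improvement) admits several estimators; the mean is the least
scale-dependent of them.

Within `crossvalidate_sweetspot()`, predictions are expressed relative
to each fold's training-mean change. The raw prediction contains the
training grand mean additively; under leave-one-out that term moves by
$-x_i/(n-1)$ with the held-out value, which alone drives the
predicted–observed correlation toward −1 under a null cohort. Centering
removes this artifact without touching genuine spatial contrast. Even
centered, cross-validated correlations of mean-type predictors retain a
small negative small-sample bias (about −0.17 at n = 24, −0.05 at
n = 56 in our null simulations) — worth remembering when interpreting
small-cohort cross-validation R values. Folds are leave-one-out or a
seeded k-fold partition; R is Pearson (Spearman by flag), and the
coverage filter is recomputed on each training set.

# Fiber filtering

Streamlines are marked connected to a patient when any vertex — or
sampled point at half-voxel steps along each segment, so thin masks
cannot be skipped — falls inside the patient's bilateral VTA. Fibers
connected to fewer than `ceiling(0.2 * N)` patients are discarded. Each
remaining fiber gets a **fiber T-score**: the pooled-variance two-sample
t statistic contrasting the outcome change of connected vs unconnected
patients (positive = connected patients improved more; Welch is
deliberately not the default, matching the classical fiber-filtering
formulation). Scores are undefined (NaN, flagged) when a group has
fewer than two members or pooled variance is zero. The top 30% by |T|
(ties broken by ascending fiber id for determinism) form the selected
set; held-out patients are predicted by the mean T of the selected
fibers their VTA touches (0, flagged, when none). Cross-validation
mirrors the sweet-spot scheme; connectivity is geometric and
outcome-free, so the fiber × patient matrix is computed once and reused
across folds without leakage.

# Clinical statistics

Improvement rate is `((pre - post) / pre) * 100` (undefined at
pre = 0, flagged; full precision retained, rounding is display-only).
Paired baseline/follow-up comparisons are gated by Shapiro–Wilk on the
differences at α = 0.05: normal → paired t (mean ± SD summaries),
otherwise Wilcoxon signed-rank (median (Q1, Q3) summaries, the same
exact/approximate machinery as the voxel test; constant differences
fall to the Wilcoxon branch with a flag). Associations between
active-contact coordinates (or VTA-subregion overlaps) and improvement
rates are Spearman correlations: rho is rank-then-Pearson; p is exact
for n ≤ 10 without ties and a t approximation otherwise. The
correlation family is reported uncorrected by default (a BH flag is
available), matching common practice for exploratory coordinate
correlations.

# The synthetic cohort generator

`make_toy_atlas()` builds an MNI-like phantom (default 64³ voxels at
0.5 mm): two mirrored ellipsoidal STNs (half-length 4 mm, half-width
1.75 mm, long axis tilted 20° from vertical so the dorsal end is
lateral), each split into equal thirds along the axis — sensorimotor
(dorsal), associative, limbic (ventral) — plus an anterior/superior
"PFC-like" box and a posterior/superior "SMC-like" box as streamline
targets. `make_electrode()` drops a vertical four-contact lead through
the ventral STN tip (contact 0 at the ventral border at offset 0, ≤
0.5 mm in-plane jitter). `make_tractogram()` draws quadratic-Bezier
streamlines from limbic voxels to the PFC box and from sensorimotor
voxels to the SMC box.

Outcomes follow a linear-additive model with Gaussian noise — the
simplest generative model under which all the pipeline's statistics are
consistent:

$$\Delta_i = w_v \frac{|VTA_i \cap S|}{|S|}
 + w_{PFC}\, c_i^{PFC} + w_{SMC}\, c_i^{SMC} + \varepsilon_i,$$

where $S$ is the planted sweet sphere (radius 2.5 mm, centered in the
ventrocentral left STN), $c_i^b$ is the fraction of bundle-b fibers
connected to patient i's bilateral VTA, and
$\varepsilon_i \sim N(0, \sigma)$. Scenario defaults:

| scenario | $w_v$ | $w_{PFC}$ | $w_{SMC}$ | $\sigma$ |
|---|---|---|---|---|
| `ventral_effect` | +8 | +0.5 | −5 | 1 |
| `tract_only` | 0 | +4 | −4 | 1 |
| `null` | 0 | 0 | 0 | 1 |

The `ventral_effect` weights were chosen once, at design time, so that
cohort change scores straddle zero: the positive sweet-sphere effect for
ventrally stimulated patients is balanced by a negative
sensorimotor-tract effect for dorsally stimulated ones. This encodes
both directions of effect the analysis is meant to detect (ventral/PFC
beneficial, dorsal/SMC detrimental), and it is what makes the planted
spot recoverable: a strictly one-signed outcome field would make every
sufficiently covered voxel "significantly positive", since a patient's
global change is attributed to all of their covered voxels. That
attribution blur is a real property of sweet-spot mapping, not of the
generator. Stimulation settings are drawn near 2.5 V / 129 Hz / 64 µs;
HAMA baselines are uniform on [5, 15] and post-scores floor at zero;
UPDRS-III, PDQ-39 and LEDD follow plausible 6-month trajectories
(≈35%, ≈25% and ≈69% reductions) so summary tables look realistic.

What the generator does **not** emulate: realistic cortical and nuclear
anatomy, registration/normalization error, FEM field shapes,
patient-specific tractography, integer-valued psychometrics, covariate
structure (age, disease duration, medication) and missing data. Passing
recovery tests therefore demonstrates the *statistical machinery* is
sound, not that real-data effect sizes will match.

# Numerical choices and test scales

- `ceiling()` implements every "at least x%" rule (coverage,
  prevalence, top fraction), making thresholds integer and exact.
- All reader/writer pairs round-trip at float32 (NIfTI, TCK, TRK);
  TRK's corner-anchored voxel-mm convention is normalized to RAS mm on
  read.
- Determinism: every stochastic step (cohort generation, jitter, k-fold
  partition) is seed-addressed; regeneration is bit-identical.
- Monte-Carlo scales used by the test suite, chosen as the package's
  own balance of power vs runtime: FDR control over 200 null cohorts of
  n = 56; null cross-validation bias over 100 cohorts of n = 56 with the
  10-fold scheme; recovery checks on the bundled seed 7 at low noise
  (σ = 0.1 or 0.5).

# Known limitations

- The point-source VTA is spherical by construction; asymmetric or
  tissue-dependent activation volumes are not representable.
- Sweet-spot attribution blur (above) limits spatial specificity at low
  cohort heterogeneity; interpret map edges cautiously.
- Cross-validated R of mean-type predictors is slightly negatively
  biased in small cohorts even under the null (see above).
- The exact improvement-rate formula is undefined at zero baselines;
  such patients are flagged and excluded from rate-based correlations.
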