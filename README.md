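# dbsmap

Group-level outcome mapping for subthalamic deep brain stimulation
(STN-DBS) in Parkinson's disease: where in and around the nucleus does
stimulation improve anxiety and depression, and which fiber pathways
carry the effect?

`dbsmap` is an R implementation of the standard DBS mapping toolchain,
exercised end to end on synthetic cohorts with planted ground truth:

- **VTA estimation** — the volume of tissue activated around the active
  contact, from a quasi-static point-source field
  `|E|(r) = U·r_c / r²` thresholded at 0.2 V/mm; for this field the VTA
  is a ball of radius `r* = sqrt(U·r_c / E_th)` (≈ 2.82 mm at 2.5 V).
- **Atlas overlap** — VTA intersection volumes with the STN and its
  sensorimotor / associative / limbic subregions.
- **Sweet-spot mapping** — an N-image of per-voxel VTA coverage, a 20%
  coverage filter (keep iff count ≥ ⌈0.2·N⌉), per-voxel mean change
  scores, two-sided Wilcoxon signed-rank tests against zero (exact
  sign-flip null for n ≤ 25, tie-corrected normal approximation
  beyond), Benjamini–Hochberg FDR at α = 0.05, and sweet (+) / sour (−)
  voxel labels.
- **Fiber filtering** — streamline–VTA connectivity (half-voxel segment
  sampling), a 20% prevalence filter, pooled-variance two-sample
  "fiber T-scores" contrasting outcomes of connected vs unconnected
  patients, and top-30%-by-|T| selection.
- **Cross-validation** — leave-one-out and seeded k-fold prediction of
  held-out outcomes from maps or fiber scores, with fold-wise refitting.
- **Clinical statistics** — improvement rates
  `((pre − post)/pre)·100`, Shapiro–Wilk-gated paired tests, and
  Spearman correlations of contact coordinates and subregion overlaps
  with improvement.
- **Synthetic cohorts** — a tripartite ellipsoidal STN phantom,
  four-contact electrodes, two-bundle tractograms (limbic→PFC-like,
  sensorimotor→SMC-like) and a linear-additive outcome model with a
  planted sweet sphere and signed tract effects.

File formats: NIfTI-1 volumes (via RNifti), MRtrix `.tck` and TrackVis
`.trk` tractograms (world RAS mm), CSV electrode/clinical tables, and a
YAML cohort manifest. The electrode CSV schema is one row per
(patient, hemisphere): `patient_id, hemisphere, c0x..c3z` (12 contact
coordinates, contact 0 most distal), `active_contact (0–3),
amplitude_v, frequency_hz, pulse_width_us, mode`.

## Worked example

The numbered scripts under `analysis/` run the full workflow on a
56-patient synthetic cohort (scenario `ventral_effect`, seed 7) and
write tables, maps and selected-fiber tractograms under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_vta_overlaps.R
Rscript analysis/03_clinical_outcomes.R
Rscript analysis/04_sweetspot_mapping.R
Rscript analysis/05_fiber_filtering.R
```

Selected output from one run:

```
Planted sweet spot: center (-5.32, 0.00, -3.88) mm, radius 2.5 mm
Effect weights: voxel +8.0, PFC bundle +0.5, SMC bundle -5.0, noise SD 1.0

Active-contact Z vs HAMA improvement (Spearman):
  left  rho = -0.798, p = 0.0000
  right rho = -0.045, p = 0.7424

Limbic-overlap vs HAMA improvement (Spearman):
  STN_left_limbic        (left electrodes) rho = +0.854, p = 0.0000
  STN_right_limbic       (right electrodes) rho = +0.039, p = 0.7736

<sweetspot_maps> outcome HAMA: 2605 kept voxels, 419 sweet, 633 sour (alpha = 0.05)
<cv_result> LOOCV (n = 56): R = 0.913, p = 9.78e-23
<cv_result> 10-fold CV (n = 56): R = 0.916, p = 4.36e-23

381/400 fibers pass the 20% prevalence filter; 112 selected (top 30% by |T|)
Selected positive-T fibers in PFC bundle: 54/54; negative-T in SMC bundle: 58/58
<cv_result> LOOCV (n = 56): R = 0.884, p = 1.88e-19
```

Reading this: the planted left-ventral sweet sphere makes improvement
decrease with the z (dorsoventral) coordinate of the left active
contact (rho = −0.80) and increase with left limbic overlap
(rho = +0.85); the voxel-wise map recovers a sweet cluster around the
sphere and a sour cluster dorsally; every selected positive-T fiber
belongs to the PFC-bound bundle and every negative-T fiber to the
sensorimotor bundle, matching the planted signs; and both spatial
models predict held-out patients' outcomes (R ≈ 0.9 at this noise
level). The vignette
(`vignettes/dbs-outcome-mapping.Rmd`) documents the models, the
generator's assumptions and its limitations.

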