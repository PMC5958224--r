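---
title: "Kinetic fluorescence phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic fluorescence phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorpheno)
```

## What this package computes

`fluorpheno` implements a complete drought-phenotyping analysis for
rosette plants imaged with pulse-amplitude-modulated (PAM) chlorophyll
fluorescence and UV-excited multicolor fluorescence:

1. a timed **quenching protocol** (dark-adapted Fo/Fm, actinic induction
   with a saturating-flash series, dark relaxation);
2. a **forward simulator** that renders per-pixel fluorescence image
   stacks from known physiological ground truth, so every downstream
   estimate has a recoverable target;
3. **image preprocessing** (Otsu background segmentation, canopy ROI,
   kinetic trace extraction, projected leaf area);
4. the **quenching parameter catalogue**: 89 chlorophyll parameters
   (Fv/Fm, NPQ, Rfd, ΦPSII, qN, qP, qL and the underlying levels at each
   flash stage) plus 16 multicolor parameters (BF, GF, RF, IrF and their
   12 ordered ratios) — 105 parameters per plant;
5. **statistics and classification**: Welch treatment comparisons with
   star coding, a thresholded Pearson correlation network, Fisher-criterion
   sequential forward selection (SFS), and stratified 10-fold
   cross-validated linear maximum-margin classification of control (label
   1) versus drought-stressed (label 2) plants.

## The quenching protocol

The default schedule (`default_quenching_protocol()`): Fo is measured with
a 4040 ms weak flash inside the initial dark window; Fm with a 320 ms
saturating flash (~2300 µmol m⁻² s⁻¹) at 5.56 s; actinic light
(100 µmol m⁻² s⁻¹) then runs for 70 s, with the induction (Kautsky) peak
Fp sampled at 23.12 s and saturating flashes at 32.24, 42.24, 52.24,
72.24 and 92.24 s (stages L1–L4 and Lss, the steady state); after
lights-off, relaxation flashes at 122.24, 152.24 and 182.24 s (D1–D3).

Two timings are not fixed by the published schedule and are set here as
package defaults, both configurable:

* **Actinic onset = 22.24 s.** This is the unique onset for which the
  70 s actinic period contains all five light-phase flashes (the Lss flash
  falls exactly at lights-off) and precedes the Fp sample. It puts Fp
  0.88 s after light-on, which is where a dark-adapted induction transient
  actually peaks.
* **Fo window start = 1.0 s** inside the dark window.

Frames are sampled at 2 Hz between events and 50 Hz inside flash windows,
so flash peaks are resolved explicitly rather than interpolated.

## The forward model

Each plant pixel carries a physiological state
(`make_truth()`): dark-adapted maximal fluorescence `fm_amp` (counts),
maximum PSII quantum yield `fvfm_true` (sets Fo = Fm·(1 − Fv/Fm)),
steady-state non-photochemical quenching `npq_ss` with induction and
relaxation rates `k_ind`, `k_rel`, and PSII operating efficiency
`phi_ss` with onset value `phi0` and induction rate `k_p`. Fluorescence
is rendered as:

* dark, measuring light: `F = Fo`; during the Fm flash: `F = Fm`;
* actinic phase: `NPQ(t) = npq_ss·(1 − e^{−k_ind·(t − t_on)})`,
  `Fm′(t) = Fm/(1 + NPQ(t))`,
  `Φ(t) = phi_ss + (phi0 − phi_ss)·e^{−k_p·(t − t_on)}`,
  `Ft(t) = Fm′(t)·(1 − Φ(t))`, and `F → Fm′(t)` during a saturating
  flash. Because `phi0` is small (0.05), `Ft` jumps to a peak just after
  light-on — the Kautsky peak that the extractor reports as Fp — and then
  declines as photochemistry and NPQ engage;
* dark relaxation: `NPQ(t) = npq_ss·e^{−k_rel·(t − t_off)}` and the
  openness recovers, so `Ft` decays toward the reopened-center level
  `Fo′(t) = Fo/(Fv/Fm + Fo/Fm′(t))`.

Within a saturating-flash window the quenching state is evaluated at the
flash onset time: a 320 ms flash neither induces nor relaxes NPQ
appreciably, and this makes the window maximum a well-defined level even
for the Lss flash that sits exactly at the lights-off boundary.

**Rate constants.** `k_ind = k_p = 0.25 s⁻¹` and `k_rel = 0.03 s⁻¹`.
The induction rates are set so the light phase reaches its asymptote to
numerical precision within the 70 s actinic period: the residual
`e^{−0.25·70} ≈ 2.5·10⁻⁸` is what makes the zero-noise identifiability
guarantee (below) hold at the 10⁻⁶ level. A slower transient
(e.g. 0.15 s⁻¹) leaves a ~3·10⁻⁵ bias in the extracted steady-state
values, which is invisible in any realistic analysis but violates the
package's own exactness contract.

**Noise.** Gaussian read noise (default SD 5 counts) plus a
signal-proportional variance term (`variance = 0.01·signal`), a Gaussian
stand-in for shot noise chosen so that seeded runs are trivially
reproducible. Background pixels carry read noise only.

## Drought presets: the stated world

No quantitative drought effect sizes are published for these parameters —
the figures report directions and significance stars only. The presets
therefore encode *directions* from the phenomenology (NPQ ↓, ΦPSII ↓ and
far-red emission ↓ under drought; blue and green phenolic emission ↑; red
emission ↑ slightly and late; Fv/Fm ↓ only at the late stage, from 0.85
to ~0.84/0.82) and *magnitudes* chosen once as standardized between-class
shifts relative to the 5% between-plant coefficient of variation:

| preset | day | shift on affected parameters |
|--------|-----|------------------------------|
| day1   | 1   | ~0.5 SD (barely detectable)  |
| day3 ("moderate") | 3 | ~2 SD |
| day5   | 5   | ~4 SD |
| day7 ("severe") | 7 | ≥8 SD on ≥5 parameters |
| day8   | 8   | slightly stronger than day7 |

Fv/Fm gets its own much smaller between-plant CV (0.003), calibrated to
the published control spread of 0.85 ± 0.002; a 5% CV on Fv/Fm would be
unphysiological for healthy rosettes.

`edge_gradient` concentrates the stress effect at leaf tips and edges:
the per-pixel effect is `base·(1 + (mult − 1)·(1 + g·(1 − d)))`, where
`d` is the normalized distance from the leaf boundary (1 at the midrib).
The amplification acts on the *effect* rather than the raw value, so a
decreasing parameter decreases fastest at tips and edges — matching the
reported spread of stress symptoms from tips and margins inward — and the
control preset (`mult = 1` or `g = 0`) stays exactly uniform.

**What the simulator does not emulate.** Real rosettes overlap, wilt and
move between days; chlorophyll content, re-absorption and leaf angle vary
within a leaf; instrument vignetting and illumination inhomogeneity are
absent; the between-plant random effect has one latent factor per
physiological field, so the 105 catalogue parameters are far more
mutually correlated than in real data. A green synthetic test therefore
establishes the *pipeline's* correctness (geometry, timing, formulas,
selection and CV machinery), not biological realism of any particular
accuracy figure.

## Parameter catalogue

`extract_basic_signals()` locates the measurable levels on the
canopy-mean trace: Fo (mean over its measuring window), Fm and every
stage Fm′ (window maxima), Fp (maximum of the actinic transient before
the first flash), pre-flash Ft levels (1 s window means; the last
pre-flash sample for Ft_Lss), and stage Fo′ values via the
Oxborough–Baker reconstruction `Fo′ = Fo/(Fv/Fm + Fo/Fm′)` — the
published parameter set uses Fo_Ln/Fo_Dn without defining their
measurement, and this reconstruction is the standard substitute (a
`measured_fo_prime` override is provided).

The 89-entry chlorophyll catalogue is a reconstruction pinned by count
(the source states only "89 images"): 36 base entries (Fo, Fm, Fv, Fp and
Ft/Fm′/Fo′/Fv′ at the eight stages) plus 53 derived entries (Fv/Fm;
Fv′/Fm′, NPQ, qN, qP, qL and ΦPSII at each stage; Rfd at L1–L4). The
composition carries a `catalogue_version` attribute so the count test
stays pinned while the enumeration remains editable.

**qL forms.** The printed source formula
`qL = qP/(Fo′/Ft)` is the reciprocal-factor variant of the standard
lake-model definition `qL = qP·(Fo′/Ft)`. The package computes the
printed form by default (`ql(..., form = "printed")`) for fidelity, and
offers `"standard"`; values of the printed form can exceed 1.

## Statistics

Treatment comparison is a per-parameter Welch two-sample test (the
two-group case of the published "ANOVA"), star-coded with strict
thresholds (*** p<0.001, ** p<0.01, * p<0.05). The correlation network
keeps Pearson edges with |r| > 0.40 and p < 0.01 (t transform, n−2 df, no
multiplicity correction, as in the source analysis). The MDA computation
follows the TBA assay chain with ε = 155 mM⁻¹ cm⁻¹ — the source prints
"Mm⁻¹", read here as mM⁻¹, the standard TBA–MDA coefficient — and
defaults of 2 mL assay, 1 mL aliquot of a 5 mL extract, 0.1 g fresh
weight, all configurable.

## Feature selection and classification

The published method names only "SFS with the Fisher criterion"; the
subset score is therefore a design choice, isolated behind one argument:

* `"decorrelated"` (default): the subset-augmented two-class Fisher score
  `J(S) = d′ S_W⁻¹ d` (class-mean difference vector, pooled unbiased
  within-class scatter). This is equivalent to summing univariate Fisher
  ratios over *within-class-whitened* components: adding a near-duplicate
  of a selected feature gains ~0, so the greedy search assembles
  complementary features.
* `"ranking"`: the classic per-feature criterion, which degenerates to
  top-k Fisher ranking — redundant, but extremely stable under
  resampling.

Both pick the plain Fisher-ratio maximizer first, and ties are broken by
feature name order, so selection is deterministic. A consequence worth
stating: because the catalogue is highly collinear, the decorrelated
criterion keeps *one representative per correlated block*, and which
named feature represents a block flips under bootstrap resampling. Its
name-level selection overlap is therefore low by construction; the
bootstrap stability smoke test in the suite is asserted on the ranking
criterion, checking that at least 5 of 9 features recur.

Classification is an L2-regularized, L1-loss linear SVM solved by dual
coordinate descent (the LIBLINEAR algorithm), with C = 1 and cyclic,
deterministic updates — implemented in-package because no SVM library is
assumed. Features are z-scored with the scaler fit on the training fold
only; folds are stratified by class and seeded. Reports give control,
drought and overall accuracy in percent, aggregated over held-out folds.

**Null-safety and selection leakage.** Running SFS on a cohort and then
cross-validating on the *same* cohort leaks the selection: even with
identically distributed classes, accuracy sits above 50%. This is the
published design (selection once, then CV), reproduced faithfully in
`run_pipeline()`; but the package's null-safety test instead evaluates
`cv_classify()` with a pre-specified nine-feature panel on a null cohort,
which is the correct chance-level check for the classifier itself.

## Numerical and degenerate-input choices

* Otsu's threshold maximizes between-class histogram variance over 256
  bins; ties resolve to the lowest threshold; a constant image is an
  error ("no plant detected").
* Connected components below `min_object_px = 50` are removed; surviving
  components are merged into one canopy ROI (pot-level analysis).
* `fisher_ratio` returns +Inf with a warning when both class variances
  vanish but means differ, 0 when the means coincide.
* Constant traits are excluded from the correlation network with a
  warning; correlation p-values guard against r² = 1 rounding.
* In `cv_classify`, a zero training-fold SD z-scores to SD 1; fold
  assignment warns when a class has fewer samples than folds.
* All simulation entry points accept a seed and restore the caller's RNG
  state; derived per-plant seeds stay below 2³¹.

## Known limitations

* Per-leaf analysis, leaf counting, day-to-day plant tracking and RGB
  morphometrics beyond projected area are out of scope.
* The simulator's kinetic model is phenomenological (exponential NPQ and
  photochemistry induction); it contains no electron-transport mechanism
  and cannot emulate OJIP fine structure.
* Frame stacks are exchanged as plain-text CSV + JSON sidecar rather than
  multi-frame TIFF (no TIFF codec is assumed in the environment); the
  format is lossless for the data sizes involved.
* Accuracy figures from synthetic cohorts depend on the preset
  calibration above and should be read as analog checks of the pipeline,
  not as reproductions of instrument-data results.
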