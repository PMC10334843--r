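---
title: "Methods: simulation and analysis of label-free adipose metabolic imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and analysis of label-free adipose metabolic imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`adipoflim` implements a complete, testable emulation of a label-free
two-photon metabolic imaging workflow for adipose tissue. The biological
setting: white adipose tissue is a mixture of adipocytes and macrophages
whose metabolic states diverge during the progression from insulin
resistance (prediabetes) to overt diabetes. Three endogenous fluorophores
carry the signal:

* **NAD(P)H** (740 nm excitation, 400–480 nm emission) and **FAD**
  (890 nm, 510–600 nm), whose intensity ratio forms the optical redox
  ratio `I_FAD / (I_NAD(P)H + I_FAD)` — lower values indicate reduced
  oxidative metabolism;
* **lipofuscin-like pigments** (1040 nm, 604–679 nm), an aging/lysosomal
  pigment whose red autofluorescence is specific to macrophages and
  therefore segments them label-free;
* the **NAD(P)H fluorescence lifetime**, modelled as a two-component decay
  `a1·exp(-t/t1) + (1-a1)·exp(-t/t2)` (free and protein-bound NAD(P)H)
  convolved with a Gaussian instrument response function (IRF).

Because no raw imaging data are publicly deposited for this kind of study,
the package ships a first-class synthetic-data layer whose ground truth
encodes the qualitative disease biology: in the *prediabetic* stage only
adipocytes shift (redox down, `a1` up, `t2` down); in the *diabetic* stage
both cell types shift, lipofuscin intensity rises (most in crown-like
structures, CLS), and CLS macrophages are configured with a lower redox
ratio than non-CLS macrophages. Every downstream stage — projection,
segmentation, redox extraction, decay fitting, the diagnostic statistics —
is validated against this known truth.

# The synthetic-data generator

## What it emulates

* **Cohorts** (`simulate_cohort`): three groups (control, HFD, HFHSD),
  8 mice per group, 16 weekly measurements of body weight, fasting glucose
  and insulin. HOMA-IR is derived as `FPG × FINS / 22.5`. Default drifts
  are chosen so that diet-group mean HOMA-IR exceeds control well before
  week 5 and group-mean fasting glucose crosses the 13 mmol/L
  hyperglycemia threshold by week 16. The drifts are linear-in-week
  simulator choices; the stated study behaviour constrains only the
  week-5 and week-16 mileposts.
* **Tissue scenes** (`generate_tissue_scene`): unilocular adipocytes are
  rendered as dark lipid voids with thin bright cytoplasm rims (annuli);
  macrophages as small disks; a CLS is a dense ring of at least five
  macrophages crowning an adipocyte. Geometry scales with the frame so
  cell density is resolution-independent. Truth masks are disjoint by
  construction with macrophage-first priority, matching the segmentation
  tie rule.
* **Image stacks** (`render_multichannel_stack`): per-pixel expected
  counts are split between the NAD(P)H and FAD channels by the owning
  cell's redox ratio, the lipofuscin channel lights up only on macrophage
  masks, and independent Poisson counts are drawn per pixel, channel and
  z-plane (11 planes ≙ 20 µm at 2 µm steps by default). The default
  full-frame geometry is 4096 px at 0.16 µm pitch (655.36 µm field).
* **TCSPC decays** (`make_irf`, `simulate_decay`, `render_flim_frame`):
  a unit-area discrete Gaussian IRF (170 ps FWHM default) convolved with
  the bi-exponential model; per-pixel Poisson draws at a photon budget
  whose default (400 expected photons per foreground pixel on a 256×256
  frame) comfortably clears the 200-count floor below which fits are
  refused.

## What it does not emulate

No optical point-spread function, scattering, depth attenuation,
photobleaching, detector afterpulsing, or instrument drift; absolute
brightness is uncalibrated by design (the source studies state no per-cell
intensity levels). Passing tests therefore demonstrate correctness of the
*analysis* under idealized image formation, not robustness to every
real-microscope artifact.

## Default metabolic truths

The per-cell means (control adipocyte redox ≈ 0.45 vs prediabetic ≈ 0.38;
`a1` 0.75 → 0.82; `t2` 2.5 → 2.2 ns; diabetic adipocytes 0.35/0.85/2.1;
macrophages unchanged until diabetes, then redox 0.38 non-CLS / 0.33 CLS,
lipofuscin 1.5× / 2.2× control) are configurable simulator choices that
encode reported effect *directions*, not published per-cell values.
Cell-level scatter (SD 0.03 on ratios, 0.12 ns on `t2`) and a shared
per-field random effect (≈half the cell SD) produce field-of-view
variability comparable to scatter seen in per-field data points.

# Numerical choices

* **Axis conventions**: 1-based pixel indices and `(y, x, channel, z)`
  array order — the natural column-major R layout used by the imaging
  packages this builds on.
* **Segmentation threshold**: the default is a deterministic two-means
  (Jenks-style) break on `log1p` intensities rather than Otsu. Otsu
  weights classes by pixel counts and, with bright cells covering well
  under 1% of the field, places its threshold inside the background noise
  (measured: ~1100 spurious components on a 512-px frame); the two-means
  boundary stays between the background and object modes regardless of
  class imbalance. Otsu remains available (`method = "otsu"`), and any
  explicit threshold overrides both.
* **CLS calling**: single-linkage clustering of macrophage centroids with
  linking distance 2× the median macrophage equivalent diameter, minimum
  5 cells per crown. The underlying studies define CLS visually only;
  these defaults are the package's operationalization.
* **Decay fitting**: Levenberg–Marquardt weighted least squares with
  Neyman weights `1/max(obs, 1)` — the common TCSPC convention — over
  `(a1, t1, t2, scale)` with bounds `t1 ∈ (0.05, 1]` ns, `t2 ∈ (1, 6]` ns
  enforcing the lifetime ordering, initialized at `a1 = 0.7`,
  `t1 = 0.4` ns, `t2 = 2.5` ns (typical free/bound NAD(P)H). Neyman
  weighting is measurably biased at low photon counts (at 2 000 photons
  the long lifetime is underestimated by roughly 10%; at 100 000 photons
  the bias is ~1%); a Poisson maximum-likelihood objective
  (`objective = "mle"`) is provided and is essentially unbiased down to a
  few hundred photons. WLS stays the default for convention and speed;
  analyses at low per-pixel counts should either bin spatially
  (`fit_flim_image(binning = ...)`, non-overlapping blocks) or switch to
  MLE. No IRF color-shift parameter is fitted.
* **Goodness of fit**: Pearson reduced chi-square over bins whose
  expected count reaches a floor (default 1), `dof = n_used - n_params`.
* **Seeding**: one master seed per top-level call; child operations
  derive substreams with `child_seed()`, which scrambles (seed, offset)
  through two Lehmer-LCG rounds. Raw arithmetic offsets fed to
  `set.seed()` produced measurably correlated streams between simulated
  groups (group-null t-tests rejected far above nominal rate across many
  master seeds); after scrambling the group-null p-values are uniform.
* **ROC/AUC**: thresholds swept over distinct scores, trapezoid
  integration; tied scores contribute averaged diagonal steps, so the AUC
  equals the normalized Mann–Whitney U exactly. The Youden point maximizes
  `TPR − FPR`; classification accuracy uses the 0.5 probability cutoff —
  the two operating points are reported separately.
* **Diagnostics**: the "integrated parameter" combining redox, `a1` and
  `t2` is the multivariable logistic score. `diagnose_groups()` reports
  ROC both on resubstitution probabilities (the conventional presentation)
  and on leave-one-out cross-validated probabilities (`roc_cv`), which are
  free of resubstitution optimism; null-feature checks should use the
  latter. The univariate screen reports raw Wald p-values (with a
  Benjamini–Hochberg column alongside, not used for screening by
  default). PCA standardizes columns before decomposition, as the
  readouts carry heterogeneous units; loadings are unit-norm with the
  largest-magnitude entry made positive.

# Unit of analysis

The field of view is the unit of analysis: each data point averages up to
10 cells of one type in one field, mirroring per-field pooling of 25–30
points from 8 animals per group. That pooling induces pseudo-replication
with respect to animals; the per-cell records returned by
`simulate_study()` retain field identifiers so a per-animal aggregation
can be layered on when needed.

# Problem sizes used in the test-suite

The packaged checks run at desk scale, as the package's own choice of
problem size: scenes of 96–512 px (the full 4096-px geometry is exercised
only through its recorded metadata), 30 fields of view per group for the
end-to-end stage-contrast study, 200 replicate decays at 10^5 photons for
the recovery study, and 1 000 simulated null tables for screening
calibration. The end-to-end property reproduced on synthetic data is the
qualitative contrast — prediabetes separable from control on adipocyte
readouts (cross-validated AUC > 0.8) but not on macrophage readouts
(cross-validated AUC statistically indistinguishable from 0.5), with both
cell types separable in diabetes — never the headline accuracy figures of
any real-data study, which are not reproducible without the original
images.

# Known limitations

* Macrophage redox ratios inherit a blended contribution in real tissue
  (lipofuscin bleeding into the FAD band); the simulator does not model
  this spectral cross-talk, so measured macrophage redox is cleaner here
  than in practice.
* Segmentation is validated only against synthetic truth; real tissue
  outlines may require manual curation or learned models, both out of
  scope.
* The decay model fits a single bi-exponential per pixel/cell; no phasor
  analysis, no image-wide global fitting, no vendor file formats.
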