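---
title: "Methods: specific CTC identification and PD-L1 evaluation with ctcgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: specific CTC identification and PD-L1 evaluation with ctcgate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcgate)
```

## The problem

Circulating tumor cells (CTCs) are conventionally identified in enriched
blood samples as pan-cytokeratin-positive, CD45-negative (pCK⁺CD45⁻) events.
That definition has a known failure mode: granulocytic and other myeloid
cells — neutrophils, myeloid-derived suppressor cells — express CD45 only
weakly ("CD45-low") and take up intracellular stains non-specifically,
including pCK and its isotype control. Under a two-marker gate these cells
are indistinguishable from tumor cells, inflate CTC counts, and, because
myeloid cells also express PD-L1, can badly skew PD-L1 biomarker readouts on
putative CTCs. Adding CD11b, an integrin expressed across the myeloid
lineage, as an exclusion marker splits the pCK⁺CD45⁻ pool into true CTCs
(CD11b⁻) and myeloid false positives (CD11b⁺).

`ctcgate` implements the complete quantification pipeline around this idea —
image cytometry, threshold derivation, sequential gating, and biomarker
summaries — together with a synthetic-data generator that plants known
population structure, so that every stage of the pipeline is validated by
recovering parameters it has never seen directly.

## The synthetic cohort

Patient material is not available for a reimplementation, so the generator
stands in for it. Each *scenario* is one sample: a mixture of cell classes
(`WBC`, `MYELOID`, `CTC`, `OTHER`), a capture antibody (EpCAM, MUC1 or Vim)
that determines the mixture composition, a cell count and a seed. Marker
intensities are log-normal per class and channel, parameterized by median
and geometric SD (GSD) — the conventional right-skewed, strictly positive
model for fluorescence. Defaults place every gated class pair at least one
decade apart in median (CD45: WBC 5000 / myeloid 250 / CTC 40; CD11b:
myeloid 3000 / others 30; pCK: CTC 150 / background 10) with GSDs of
1.6–1.8, which is what makes valley-based thresholding well-posed; the
noise floor and these separations are properties of the emulated assay, not
tuning knobs.

Scenario presets encode the study conditions as planted truths:

* `fig1_flow` — three CD45-depleted buffy-coat patients; myeloid:comparator
  staining ratios planted at {8, 9, 22}× for pCK (mean 13) and
  {12, 19, 38}× for the isotype control (mean 23). Endpoints come from the
  reported ranges; the middle value is forced by the reported mean.
* `fig2d_capture` — one patient captured in parallel with EpCAM, MUC1 and
  Vim; planted myeloid fractions 0.22, 0.27, 0.47.
* `fig2e_capture` — five patients × three antibodies. Only the group means
  (EpCAM 18%, MUC1 20%, Vim 41%) and the overall range (3–66%) are
  reported; the per-patient vectors here are constrained choices that
  reproduce those statistics and the reported test outcomes (Vim captures
  significantly more CD11b⁺ cells than either alternative; EpCAM vs MUC1
  not significant).
* `fig3_falsepos` — four patients × {EpCAM, MUC1}; contamination of the
  standard-identified CTC pool planted at {33, 71, 100, 100}% for EpCAM
  (mean 76%) and {33, 63, 100, 100}% for MUC1 (mean 74%, same
  endpoints-plus-mean construction).
* `fig4_pdl1` — seven MUC1 patients with planted contamination rising from
  20% to 80% and per-patient CTC PD-L1 medians spanning 25–120 units
  against a fixed myeloid PD-L1 median of 250; no per-patient values are
  reported for this experiment, so these vectors are synthetic by
  construction and are labelled as such.
* `s1_muc1` — four patients with planted false-positive fractions
  {10, 12, 10, 20}% (mean 13%).

Each scenario stores `planted` summaries recomputed analytically from its
parameters (`planted_summaries()`), and `check_scenario()` verifies the
stored values against a fresh recomputation to 1e-9 — so a preset can never
drift away from the numbers it claims to plant.

Event mode (`sample_events()`) draws class memberships multinomially and
intensities log-normally, emulating a flow-cytometry readout. A fixed seed
gives byte-identical output; membership, intensity and size streams are
separated, so the image renderer consumes exactly the intensities the event
table reports.

## The image renderer

`render_sample()` turns an event table into what the microscope would hand
the pipeline: cells placed by rejection sampling (default 5% deliberately
touching a neighbour at 0.85× the radius sum), nuclei as filled discs in
the Hoechst channel, all other markers over a cytoplasm disc 3 px larger,
per-channel background (default 500 units), Gaussian read noise (SD 50),
16-bit clipping, and a 2×2 tile grid with 10% overlap. Where discs overlap,
each pixel carries the amplitude of the nearest covering cell — cells are
opaque, and stain mixing or spectral bleed-through is deliberately not
modelled. The ground-truth label mask is taken before noise; contested
nucleus pixels go to the nearer centroid, so every placed cell keeps
exactly one label even in touching pairs.

The renderer retains the un-tiled field, which gives the stitcher an exact
oracle: tiles are cut from one field, so overlapping strips are identical
and the stitched reconstruction must equal the field pixel for pixel.

What the simulation does *not* emulate matters for interpreting green
tests: there is no point-spread function, no illumination gradient, no
focus drift, no debris or autofluorescence, and real per-cell staining is
not exactly log-normal. Passing recovery tests demonstrates that the
pipeline is unbiased under its stated model, not that segmentation would be
this clean on clinical slides.

## Image cytometry

`run_image_pipeline()` composes four stages.

**Stitching** places tiles at the offsets recorded in the layout sidecar
(registration is configuration, never estimated) and averages overlapping
pixels.

**Background subtraction** estimates the per-channel background and clamps
`pixel − b` at zero. Two estimators are provided. The global median is
exact on an empty field, but with ~18% of pixels covered by cells it sits a
little way up the noise distribution (≈ +14 units at the default noise SD),
which biases every faint MFI downward. The default is therefore a two-pass
scheme: a median-based first pass finds nuclei, then the background is
re-estimated as the mean of pixels well clear of any detected cell (nuclear
mask grown past the cytoplasm extent). On rendered fields this recovers the
planted 500 to within a unit.

**Segmentation** binarizes Hoechst at a user-defined threshold (default
2000, several noise SDs above zero and a decade below the dimmest planted
nucleus), labels components with 8-connectivity, drops components below
`min_area` (10 px), and splits components containing two or more
distance-transform maxima at least `split_min_distance` (5 px) apart with a
watershed seeded at those maxima — the mechanism that separates touching
cells by their individual nuclei. Flooding processes pixels in descending
distance order with ties broken toward the lowest label, so results are
deterministic. Coordinates are 0-based row/col throughout.

**Measurement** takes, per nucleus, a region grown by an exact Euclidean
dilation of 3 px (approximating "cellular" intensity; the nucleus-only
alternative is `cytoplasm_dilation = 0`), with contested pixels assigned to
the nearest label, and reports the arithmetic mean of each channel over the
region. Area and centroid come from the undilated nucleus.

One caveat is inherent to clipped measurements: markers whose true level
sits below the read-noise floor (e.g. planted median 30 against noise SD
50) are floored upward by the zero clamp — `E[max(N(30, 50), 0)] ≈ 38`.
Cross-mode agreement between event tables and image measurements is
therefore only claimed, and only tested, for markers above the noise floor;
gating is unaffected because every derived cutoff sits far above it.

## Threshold derivation and gating

The study sets thresholds by eye on clustered populations of a
representative sample and then applies them uniformly. `derive_threshold()`
automates the same rationale: log10-transform, Gaussian KDE with
Silverman's bandwidth, cutoff at the density minimum between the two
highest modes. Three guards make the mode search well-behaved, with
defaults chosen once: modes closer than 0.3 decades to a higher mode are
treated as ripples of the same cluster (the gated populations are planted
≥ 1 decade apart); the valley must dip below 0.75 of the lower mode's
density; and each side of the cutoff must hold at least 1% of events. A
distribution failing these is reported as `no_valley` rather than given an
arbitrary cutoff — on 100 unimodal log-normal controls this produces zero
false valleys.

`derive_thresholds()` derives cutoffs once, on the representative sample
(by default the first of the batch — mirroring "a representative patient
sample" without inventing a selection statistic), records provenance, and
`classify_batch()` applies them verbatim across the batch. Re-deriving per
sample is possible but never the default.

PD-L1 needs one extra rule: expression is continuous, and a minority
PD-L1-high class one decade from the bulk produces a shoulder rather than a
separated mode, so the valley search can legitimately fail. In that case
the positivity cutoff falls back to the 99th percentile of PD-L1 among
CD45⁺ (leukocyte reference) events of the representative sample — the usual
negative-reference rule in cytometry — and is flagged `wbc_quantile` in the
provenance.

Classification follows the two gating trees. Standard: `CTC_standard` =
pCK ≥ cutoff and CD45 < cutoff; CD45-low and CD45-negative events are
deliberately not distinguished, which is exactly how myeloid cells slip
through. Strict: standard CTCs with CD11b ≥ cutoff are relabelled
`MYELOID_FP`; the rest are `CTC_strict`. By construction strict ⊆ standard
and `MYELOID_FP` is exactly the set difference — the tests assert both as
identities, along with the count-weighted decomposition of standard-pool
PD-L1 MFI into its strict and false-positive parts.

Arbitrary 1-D, rectangular and polygon gates (`gate()`, `run_strategy()`)
support the same sequential-exclusion audit trail; boundary points always
count as inside (a deterministic tie-break), and exclusion is final once a
gate removes an event. The per-gate in/out counts are recorded as a
first-class output. Cell "size" axes are areas in pixels.

## Biomarker summaries and statistics

`pdl1_summary()` reports, side by side per sample: event counts under both
definitions, the CD11b⁺ fraction of all captured events, the
false-positive fraction `n(MYELOID_FP) / n(CTC_standard)`, and PD-L1 mean
MFI and positive fraction over each CTC set. Arithmetic means are used for
MFI (the reported "average MFI" does not specify; arithmetic is the
convention for per-cell averages). Ratios with empty denominators are
flagged `NA` with a reason, never silently zero, so batch means cannot be
skewed by degenerate samples.

`ctc_t_test()` computes the classical Student t on paired differences and
the Welch form for unpaired comparisons (the safer default when only
"unpaired" is stated), with p-values from the t distribution and
significance declared strictly below α = 0.05. One-tailed tests require an
explicit direction parameter; the hypothesized direction is never implied
silently. No multiple-testing correction is applied, matching the source
analyses; reports state the number of tests run. The suite holds the
implementation to 1e-9 agreement with `stats::t.test()` and to a null
rejection rate of 0.05 ± 0.015 over 1000 replicates.

## Problem sizes and determinism

The validation analyses use 5000 events per sample for the fold-change
cohort and 2000 per sample elsewhere. These sizes are chosen from the
recovery bands: a ±3-point band on a 47% fraction needs n ≥ 1845 for 99%
binomial coverage, and 5000 events put the Monte-Carlo error of a
fold-change mean near 2% against a ±10% band. Rendered fields are sized so
cells cover ≈18% of the field. Every stage is seeded; a scenario's seed
fixes membership, intensities, placement and noise through separate
derived streams, and the end-to-end pipeline is byte-stable under a fixed
seed.

## Known limitations

* The generator's realism limits what green tests prove (see above); in
  particular segmentation precision/recall ≥ 0.95 is demonstrated on
  disc-shaped nuclei at the default noise, not on real morphology.
* Valley thresholds assume the gated populations are well separated
  (≥ 1 decade planted); closer populations will correctly produce
  `no_valley` but then require manual cutoffs.
* Touching-cell splitting uses nuclear geometry only; pathological overlap
  (centroid distance below the split minimum distance) merges cells, which
  is why a few events per thousand are lost in image mode.
* The per-patient vectors of `fig2e`/`fig3`(MUC1)/`fig4` are constrained
  synthetic choices, not measured values; only their summary statistics are
  anchored to reported numbers.
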