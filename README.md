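# ctcgate

Image cytometry and sequential gating for *specific* circulating tumor
cell (CTC) identification, with a verifiable synthetic-data generator.

## The problem

Liquid biopsies identify CTCs in enriched blood samples as
pan-cytokeratin-positive, CD45-negative (pCK⁺CD45⁻) events. Myeloid cells
— neutrophils, MDSCs — break this definition: they express CD45 only
weakly, stain non-specifically for intracellular antibodies including pCK,
and express PD-L1. Under a two-marker gate they are counted as CTCs, and
because their PD-L1 is high they can dominate a patient's "CTC PD-L1"
readout. Adding CD11b as a third, exclusion marker splits the pCK⁺CD45⁻
pool into true CTCs (CD11b⁻) and myeloid false positives (CD11b⁺):

```
            standard:   CTC_standard = pCK ≥ c_pCK  &  CD45 < c_CD45
            strict:     CTC_strict   = CTC_standard &  CD11b < c_CD11b
                        MYELOID_FP   = CTC_standard \ CTC_strict
    false-positive fraction = n(MYELOID_FP) / n(CTC_standard)
```

Thresholds `c_·` are derived by kernel-density valley finding on
log-intensities of one representative sample (Silverman bandwidth, cutoff
at the density minimum between the two dominant modes) and applied
uniformly across a batch.

`ctcgate` implements the full pipeline for both input modes:

* **image mode** — multi-channel 16-bit TIFF tiles + JSON layout sidecar
  → stitch → background subtraction → Hoechst nuclear segmentation with
  watershed splitting of touching cells → per-cell mean fluorescence
  intensities (MFI);
* **event mode** — per-cell intensity tables (CSV/ARFF), emulating a flow
  cytometry readout;

plus gating, per-sample biomarker summaries (CD11b⁺ capture fraction,
false-positive fraction, PD-L1 MFI and positivity under both CTC
definitions), and paired/unpaired t-test reports.

Because no patient data are distributable, the package ships a seeded
generator whose scenario presets plant published summary statistics as
ground truth (myeloid capture fractions of 22/27/47% by EpCAM/MUC1/Vim,
false-positive fractions averaging 76%, non-specific staining fold-changes
averaging 13× for pCK and 23× for its isotype control, and PD-L1 skew
scenarios). Every pipeline stage is validated by recovering those planted
values end to end.

## Worked example

Simulate the three-antibody capture experiment, run the full image
pipeline on rendered tiles, and summarize:

```r
library(ctcgate)

res <- run_image_analysis("fig2d_capture", n_cells = 2000, seed = 100)
res$summaries[, c("sample_id", "n_events", "cd11b_fraction", "fp_fraction")]
#>     sample_id n_events cd11b_fraction fp_fraction
#> 1 fig2d_EpCAM     1997      0.2178267   0.5745938
#> 2  fig2d_MUC1     1990      0.2653266   0.6464238
#> 3   fig2d_Vim     1992      0.4934739   0.8116214
```

Reading: of ~2000 cells rendered per sample (a handful are lost to
touching-cell merges), the measured CD11b⁺ fraction recovers the planted
capture contamination — 22% for EpCAM, 27% for MUC1, 47% for Vim (the
mesenchymal capture antigen pulls down far more myeloid cells). The
`fp_fraction` column shows what that contamination does to standard CTC
identification: in the Vim sample, 81% of events meeting pCK⁺CD45⁻ are
actually CD11b⁺ myeloid cells.

The same analysis in event mode, with significance tests across five
simulated patients:

```r
cap <- run_capture_analysis("fig2e_capture", seed = 100)
rep <- build_report(cap$summaries, value = "cd11b_fraction",
                    paired = TRUE, tails = 1, direction = "less")
rep$tests
#>   group_a group_b          t df          p stars
#> 1   EpCAM    MUC1 -0.6126135  4 0.28662387
#> 2   EpCAM     Vim -3.5084652  4 0.01235309     *
#> 3    MUC1     Vim -2.7117943  4 0.02671902     *
```

Vim captures significantly more CD11b⁺ cells than either EpCAM or MUC1
(one-tailed paired t, p < 0.05), while EpCAM and MUC1 do not differ — the
qualitative pattern the gating is meant to expose.

The numbered scripts under `analysis/` run the whole study in order
(simulate → image pipeline → classify → summarize → report), writing
tables under `results/`.

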