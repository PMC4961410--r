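#!/usr/bin/env Rscript
# Per-sample biomarker summaries under both CTC definitions: event counts,
# CD11b+ capture fraction, false-positive fraction, PD-L1 MFI and
# positivity. One CSV per preset.

library(ctcgate)

cls_dir <- file.path("results", "classified")
out <- file.path("results", "summaries")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
if (!dir.exists(cls_dir))
  stop("run analysis/03_gate_and_classify.R first")

for (name in c("fig2d_capture", "fig2e_capture", "fig3_falsepos",
               "fig4_pdl1", "s1_muc1", "fig2d_image")) {
  csv <- file.path(cls_dir, paste0(name, "_classified.csv"))
  if (!file.exists(csv)) next
  cl <- read_events_csv(csv)
  # thresholds travel with the classified batch; recover the cutoffs used
  thy <- file.path(cls_dir, paste0(sub("_image$", "_capture", name),
                                   "_thresholds.yaml"))
  if (!file.exists(thy))
    thy <- file.path(cls_dir, "fig2d_capture_thresholds.yaml")
  th <- yaml::read_yaml(thy)
  s <- summarize_batch(cl,
                       pdl1_cutoff = th$cutoffs$PDL1,
                       cd11b_cutoff = th$cutoffs$CD11b)
  s$patient <- sub("_(EpCAM|MUC1|Vim)$", "", s$sample_id)
  write.csv(s, file.path(out, paste0(name, "_summaries.csv")),
            row.names = FALSE)
  cat(sprintf("%-14s mean CD11b+ %5.1f%%  mean FP %s\n", name,
              100 * mean(s$cd11b_fraction, na.rm = TRUE),
              if (all(is.na(s$fp_fraction))) "  n/a" else
                sprintf("%5.1f%%", 100 * mean(s$fp_fraction, na.rm = TRUE))))
}
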