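#!/usr/bin/env Rscript
# Derive thresholds on each batch's representative sample, apply them
# uniformly, and classify every event through the standard (pCK+CD45-) and
# strict (CD11b-exclusion) CTC definitions. Writes labeled events and the
# thresholds used.

library(ctcgate)

seed <- 100
sim_dir <- file.path("results", "simulated")
out <- file.path("results", "classified")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
if (!dir.exists(sim_dir))
  stop("run analysis/01_simulate_cohort.R first")

for (preset in c("fig2d_capture", "fig2e_capture", "fig3_falsepos",
                 "fig4_pdl1", "s1_muc1")) {
  events <- read_events_csv(file.path(sim_dir, paste0(preset, "_events.csv")))
  cl <- classify_batch(events)
  th <- attr(cl, "thresholds")
  write_events_csv(cl, file.path(out, paste0(preset, "_classified.csv")))
  yaml::write_yaml(list(cutoffs = as.list(th$cutoffs),
                        provenance = th$provenance),
                   file.path(out, paste0(preset, "_thresholds.yaml")))
  tab <- table(cl$class_label)
  cat(sprintf("%-14s rep=%s cutoffs[CD45=%.0f CD11b=%.0f pCK=%.0f] %s\n",
              preset, th$provenance$representative_sample,
              th$cutoffs["CD45"], th$cutoffs["CD11b"], th$cutoffs["pCK"],
              paste(names(tab), tab, sep = ":", collapse = " ")))
}

# image-mode events, if 02 has been run
img_csv <- file.path("results", "image_mode", "fig2d_image_events.csv")
if (file.exists(img_csv)) {
  cl <- classify_batch(read_events_csv(img_csv))
  write_events_csv(cl, file.path(out, "fig2d_image_classified.csv"))
  cat("image-mode fig2d classified:", nrow(cl), "events\n")
}
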