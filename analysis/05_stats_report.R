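#!/usr/bin/env Rscript
# Figure-level statistics: fold-change recovery, capture-antibody
# comparisons with paired one-tailed t tests, false-positive comparison,
# and the PD-L1 standard-vs-strict paired comparison. Markdown + CSV.

library(ctcgate)

seed <- 100
sum_dir <- file.path("results", "summaries")
out <- file.path("results", "report")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# fold changes come straight from the flow-style preset
sim1 <- simulate_preset("fig1_flow", seed = seed)
fc <- analyze_fold_changes(sim1$events)
write.csv(fc, file.path(out, "fold_changes.csv"), row.names = FALSE)
cat(sprintf("pCK fold-change per patient: %s (mean %.1f)\n",
            paste(sprintf("%.1f", fc$ratio_pCK), collapse = " "),
            mean(fc$ratio_pCK)))
cat(sprintf("isotype fold-change per patient: %s (mean %.1f)\n",
            paste(sprintf("%.1f", fc$ratio_isotype), collapse = " "),
            mean(fc$ratio_isotype)))

read_sum <- function(name) {
  p <- file.path(sum_dir, paste0(name, "_summaries.csv"))
  if (!file.exists(p)) stop("run analysis/04_biomarker_summaries.R first")
  read.csv(p)
}

# capture-antibody comparison over five patients; the hypothesized
# direction is that Vim captures MORE CD11b+ cells than the alternatives,
# i.e. alphabetical group A (EpCAM/MUC1) is LESS than Vim
s2 <- read_sum("fig2e_capture")
rep2 <- build_report(s2, value = "cd11b_fraction", paired = TRUE,
                     tails = 1, direction = "less")
write_report(rep2, file.path(out, "fig2e_capture.md"),
             file.path(out, "fig2e_capture_groups.csv"))
print(rep2$tests)

# false-positive fraction: EpCAM vs MUC1, two-tailed paired
s3 <- read_sum("fig3_falsepos")
rep3 <- build_report(s3, value = "fp_fraction", paired = TRUE, tails = 2)
write_report(rep3, file.path(out, "fig3_falsepos.md"),
             file.path(out, "fig3_falsepos_groups.csv"))

# PD-L1 with vs without CD11b exclusion, paired across seven patients
s4 <- read_sum("fig4_pdl1")
tt_mfi <- ctc_t_test(s4$pdl1_mfi_standard, s4$pdl1_mfi_strict,
                     paired = TRUE, tails = 2)
tt_pos <- ctc_t_test(s4$pdl1_pos_freq_standard, s4$pdl1_pos_freq_strict,
                     paired = TRUE, tails = 2)
cat("PD-L1 MFI, standard vs strict: "); print(tt_mfi)
cat("PD-L1 positive fraction, standard vs strict: "); print(tt_pos)
writeLines(c(
  "# PD-L1 evaluation under standard vs strict CTC identification", "",
  sprintf("Mean PD-L1 MFI: standard %.1f vs strict %.1f (paired t = %.2f, p = %.4g%s)",
          mean(s4$pdl1_mfi_standard), mean(s4$pdl1_mfi_strict),
          tt_mfi$statistic, tt_mfi$p_value,
          if (tt_mfi$significant) " *" else ""),
  sprintf("PD-L1+ fraction: standard %.2f vs strict %.2f (paired t = %.2f, p = %.4g%s)",
          mean(s4$pdl1_pos_freq_standard), mean(s4$pdl1_pos_freq_strict),
          tt_pos$statistic, tt_pos$p_value,
          if (tt_pos$significant) " *" else "")),
  file.path(out, "fig4_pdl1.md"))
cat("reports under", out, "\n")
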