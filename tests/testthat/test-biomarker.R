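# Biomarker summaries: false-positive fraction, CD11b fraction,
# fold-changes, PD-L1 under the two criteria, batch aggregation.

test_that("false-positive fraction counts myeloid FPs over the standard pool", {
  expect_equal(false_positive_fraction(
    c("CTC_strict", "MYELOID_FP", "MYELOID_FP")), 2 / 3)
  expect_equal(false_positive_fraction(c("CTC_strict", "WBC")), 0)
  und <- false_positive_fraction(c("WBC", "OTHER"))
  expect_true(is_flagged(und))
})

test_that("CD11b fraction handles all-negative and empty tables", {
  ev <- data.frame(CD11b = c(10, 20, 30))
  expect_equal(cd11b_fraction(ev, 100), 0)
  expect_true(is_flagged(cd11b_fraction(ev[0, , drop = FALSE], 100)))
})

test_that("population fold-change is a ratio of group means", {
  ev <- data.frame(pCK = c(130, 130, 10, 10))
  lab <- c("A", "A", "B", "B")
  expect_equal(population_fold_change(ev, lab, "A", "B", "pCK"), 13)
  expect_equal(population_fold_change(ev, lab, "A", "A", "pCK"), 1)
  expect_true(is_flagged(population_fold_change(ev, lab, "A", "C", "pCK")))
})

test_that("PD-L1 summary decomposes exactly and standard > strict when
           myeloid PD-L1 is planted high", {
  sim <- simulate_preset("fig4_pdl1", n_cells = 2000, seed = 100)
  cl <- classify_batch(sim$events)
  s <- summarize_batch(cl)
  mid <- s[s$n_myeloid_fp > 0 & s$n_ctc_strict > 0, ]
  expect_true(all(mid$pdl1_mfi_standard > mid$pdl1_mfi_strict))
  # exact decomposition: standard mean = count-weighted mean of the parts
  for (i in seq_len(nrow(mid))) {
    ev <- cl[cl$sample_id == mid$sample_id[i], ]
    fp_mean <- mean(ev$PDL1[ev$class_label == "MYELOID_FP"])
    recomposed <- (mid$pdl1_mfi_strict[i] * mid$n_ctc_strict[i] +
                     fp_mean * mid$n_myeloid_fp[i]) / mid$n_ctc_standard[i]
    expect_equal(mid$pdl1_mfi_standard[i], recomposed)
  }
})

test_that("removing CD11b-positive events reproduces the strict summary
           under the standard criterion", {
  sim <- simulate_preset("fig3_falsepos", n_cells = 1500, seed = 100)
  cl <- classify_batch(sim$events)
  th <- attr(cl, "thresholds")
  one <- cl[cl$sample_id == "fig3_patient2_EpCAM", ]
  full <- pdl1_summary(one, pdl1_cutoff = th$cutoffs[["PDL1"]])
  dep <- one[one$CD11b < th$cutoffs[["CD11b"]], ]
  dep$class_label <- classify_strict(dep, th)
  depleted <- pdl1_summary(dep, pdl1_cutoff = th$cutoffs[["PDL1"]])
  expect_equal(depleted$pdl1_mfi_standard, full$pdl1_mfi_strict)
  expect_equal(depleted$n_ctc_standard, full$n_ctc_strict)
})

test_that("summaries are invariant under event reordering", {
  sim <- simulate_preset("s1_muc1", n_cells = 1000, seed = 100)
  cl <- classify_batch(sim$events)
  th <- attr(cl, "thresholds")
  one <- cl[cl$sample_id == "s1_patient1", ]
  set.seed(9)
  shuf <- one[sample(nrow(one)), ]
  a <- pdl1_summary(one, th$cutoffs[["PDL1"]], th$cutoffs[["CD11b"]])
  b <- pdl1_summary(shuf, th$cutoffs[["PDL1"]], th$cutoffs[["CD11b"]])
  expect_equal(a, b)
})

test_that("batch comparison reports means/ranges and enforces pairing", {
  s <- data.frame(sample_id = letters[1:2], capture_antibody = "Vim",
                  cd11b_fraction = c(0.4, 0.4))
  bc <- batch_compare(s)
  expect_equal(bc$table$min, bc$table$max)
  bad <- data.frame(sample_id = letters[1:4],
                    capture_antibody = rep(c("Vim", "EpCAM"), each = 2),
                    patient = c("p1", "p2", "p1", "p3"),
                    cd11b_fraction = runif(4))
  expect_error(batch_compare(bad, paired = TRUE),
               class = "ctcgate_pairing_error")
  expect_error(batch_compare(s[1, , drop = FALSE]),
               class = "ctcgate_validation_error")
})
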