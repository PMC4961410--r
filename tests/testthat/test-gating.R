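# Threshold derivation, gate regions, sequential strategies and the
# standard/strict classifiers.

test_that("the valley cutoff separates two point clusters", {
  v <- c(rep(1, 100), rep(10, 100))
  th <- derive_threshold(v)
  expect_equal(th$status, "ok")
  expect_gt(th$cutoff, 1)
  expect_lt(th$cutoff, 10)
})

test_that("valley cutoff on a 2-decade log-normal mixture lands in [100, 400]
           with < 1% misclassification", {
  set.seed(17)
  lab <- rbinom(5000, 1, 0.5)
  v <- ifelse(lab == 1, rlnorm(5000, log(2000), log(1.8)),
              rlnorm(5000, log(20), log(1.8)))
  th <- derive_threshold(v)
  expect_equal(th$status, "ok")
  expect_gte(th$cutoff, 100)
  expect_lte(th$cutoff, 400)
  expect_lt(mean((v >= th$cutoff) != (lab == 1)), 0.01)
})

test_that("unimodal samples report no_valley; tiny samples error", {
  set.seed(23)
  th <- derive_threshold(rlnorm(3000, log(100), log(1.8)))
  expect_equal(th$status, "no_valley")
  expect_true(is.na(th$cutoff))
  expect_error(derive_threshold(rlnorm(30, 0, 1)),
               class = "ctcgate_validation_error")
})

test_that("1-D and rectangle gates follow the boundary-inside rule", {
  ev <- data.frame(CD45 = c(5, 7, 9), area = c(10, 10, 10))
  g <- gate("CD45", "include", threshold = 7, polarity = ">=")
  expect_equal(apply_gate(ev, g), c(FALSE, TRUE, TRUE))
  gr <- gate("CD45", "include", y_axis = "area", rect = c(0, 10, 0, 10))
  pt <- data.frame(CD45 = 10, area = 10)
  expect_true(apply_gate(pt, gr))
})

test_that("polygon gates agree with an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  set.seed(5)
  for (rep in 1:5) {
    # random star-shaped (hence simple) polygon around a center
    k <- sample(5:9, 1)
    ang <- sort(runif(k, 0, 2 * pi))
    rad <- runif(k, 2, 6)
    poly <- cbind(5 + rad * cos(ang), 5 + rad * sin(ang))
    px <- runif(1000, -2, 12); py <- runif(1000, -2, 12)
    ours <- point_in_polygon(px, py, poly)
    bnd <- rbind(poly, poly[1, ])
    oracle <- mgcv::in.out(bnd, cbind(px, py))
    expect_equal(ours, oracle)
  }
})

test_that("standard classification assigns the three coarse classes", {
  th <- structure(list(cutoffs = c(pCK = 50, CD45 = 1000, CD11b = 300)),
                  class = "threshold_set")
  ev <- data.frame(pCK = c(200, 200, 5), CD45 = c(10, 5000, 10),
                   CD11b = c(10, 10, 10))
  expect_equal(classify_standard(ev, th),
               c("CTC_standard", "WBC", "OTHER"))
})

test_that("strict classification relabels CD11b-positive standard CTCs and is
           a subset of the standard set", {
  th <- structure(list(cutoffs = c(pCK = 50, CD45 = 1000, CD11b = 300)),
                  class = "threshold_set")
  ev <- data.frame(pCK = c(200, 200, 200), CD45 = c(10, 10, 5000),
                   CD11b = c(3000, 10, 3000))
  lab <- classify_strict(ev, th)
  expect_equal(lab, c("MYELOID_FP", "CTC_strict", "WBC"))
  # subset + exact decomposition on a simulated table
  sim <- simulate_preset("fig3_falsepos", n_cells = 800, seed = 100)
  cl <- classify_batch(sim$events)
  std <- classify_standard(cl, attr(cl, "thresholds")) == "CTC_standard"
  strict <- cl$class_label == "CTC_strict"
  fp <- cl$class_label == "MYELOID_FP"
  expect_true(all(strict | fp == std))
  expect_true(!any(strict & fp))
})

test_that("raising the CD11b cutoff never shrinks the strict-CTC set", {
  sim <- simulate_preset("fig3_falsepos", n_cells = 800, seed = 100)
  ev <- sim$events
  base <- derive_thresholds(ev[ev$sample_id == ev$sample_id[1], ],
                            channels = c("CD45", "CD11b", "pCK"))
  sizes <- vapply(c(100, 300, 1000, 3000, 1e5), function(cut) {
    th <- base
    th$cutoffs["CD11b"] <- cut
    sum(classify_strict(ev, th) == "CTC_strict")
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("the standard definition admits planted myeloid cells; the strict
           definition recovers truth labels at >= 95% agreement", {
  sim <- simulate_preset("fig3_falsepos", n_cells = 2000, seed = 100)
  cl <- classify_batch(sim$events)
  one <- cl[cl$sample_id == "fig3_patient1_EpCAM", ]
  std_truth <- one$truth_class[one$class_label %in%
                                 c("CTC_strict", "MYELOID_FP")]
  expect_true(all(c("CTC", "MYELOID") %in% std_truth))
  # strict labels, mapped to truth classes
  map <- c(CTC_strict = "CTC", MYELOID_FP = "MYELOID", WBC = "WBC",
           OTHER = "OTHER")
  agree <- mean(map[one$class_label] == one$truth_class)
  expect_gte(agree, 0.95)
})

test_that("sequential strategies retain/exclude as ordered and record an
           audit trail", {
  sim <- simulate_preset("fig2d_capture", n_cells = 2000, seed = 100)
  ev <- sim$events[sim$events$sample_id == "fig2d_Vim", ]
  th <- derive_thresholds(ev, channels = c("CD45", "CD11b"))
  all_in <- gating_strategy(list(
    gate("CD45", "include", threshold = 0, polarity = ">=")), "ALL")
  kept <- run_strategy(ev, all_in)
  expect_true(all(kept$gate_label == "ALL"))

  strat <- gating_strategy(list(
    gate("CD45", "exclude", threshold = th$cutoffs["CD45"], polarity = ">=",
         label = "WBC"),
    gate("CD11b", "exclude", threshold = th$cutoffs["CD11b"], polarity = ">=",
         label = "MYELOID_FP")), "CTC")
  out <- run_strategy(ev, strat)
  retained <- mean(out$gate_label == "CTC")
  planted <- 1 - 0.47 - 0.8 * (1 - 0.47)  # 1 - myeloid - wbc
  ci <- binom_ci99(sum(out$gate_label == "CTC"), nrow(ev))
  expect_gte(planted, ci[1] - 0.02)
  expect_lte(planted, ci[2] + 0.02)
  counts <- attr(out, "gate_counts")
  expect_equal(counts$n_in[1], nrow(ev))
  expect_equal(counts$n_out[2], sum(out$gate_label == "CTC"))

  # disjoint exclusions commute
  swapped <- run_strategy(ev, gating_strategy(rev(strat$gates), "CTC"))
  expect_equal(out$gate_label == "CTC", swapped$gate_label == "CTC")
})
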