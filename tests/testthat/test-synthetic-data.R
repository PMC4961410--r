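# Event-table generator: planted-parameter recovery, determinism, and
# scenario validation.

test_that("degenerate zero-spread populations reproduce planted medians exactly", {
  sc <- one_pop_scenario(n_cells = 50, seed = 3, gsd = 1)
  ev <- sample_events(sc)$events
  expect_equal(nrow(ev), 50)
  expect_true(all(ev$pCK == 150))
  expect_true(all(ev$CD45 == 40))
  expect_true(all(ev$Hoechst == 20000))
})

test_that("planted median ratios are recovered by Monte Carlo at n = 10000", {
  sc <- two_pop_scenario(n_cells = 10000, seed = 1)
  ev <- sample_events(sc)$events
  med_a <- median(ev$pCK[ev$truth_class == "MYELOID"])
  med_b <- median(ev$pCK[ev$truth_class == "OTHER"])
  expect_lt(abs(med_a / med_b - 13) / 13, 0.02)
})

test_that("capture presets plant the reported myeloid frequencies", {
  scen <- make_scenario("fig2d_capture")
  expect_named(scen, c("fig2d_EpCAM", "fig2d_MUC1", "fig2d_Vim"))
  freqs <- vapply(scen, function(s)
    s$planted$frequencies[["MYELOID"]], numeric(1))
  expect_equal(unname(freqs), c(0.22, 0.27, 0.47))
  # observed fraction within the exact binomial 99% CI of the Vim parameter
  ev <- sample_events(scen$fig2d_Vim)$events
  k <- sum(ev$truth_class == "MYELOID")
  ci <- binom_ci99(k, nrow(ev))
  expect_gte(0.47, ci[1])
  expect_lte(0.47, ci[2])
})

test_that("buffy-coat preset plants fold-change vectors with the reported means", {
  scen <- make_scenario("fig1_flow")
  pck <- vapply(scen, function(s) s$planted$pck_ratio, numeric(1))
  iso <- vapply(scen, function(s) s$planted$isotype_ratio, numeric(1))
  expect_equal(unname(pck), c(8, 9, 22))
  expect_equal(mean(pck), 13)
  expect_equal(unname(iso), c(12, 19, 38))
  expect_equal(mean(iso), 23)
})

test_that("planted summaries are self-consistent across all presets", {
  for (preset in c("fig1_flow", "fig2d_capture", "fig2e_capture",
                   "fig3_falsepos", "fig4_pdl1", "s1_muc1")) {
    scen <- make_scenario(preset)
    for (sc in scen) expect_true(check_scenario(sc, tol = 1e-9))
  }
})

test_that("class fractions fall within the binomial 99% CI of planted frequencies", {
  scen <- make_scenario("fig3_falsepos", n_cells = 1500)
  for (sc in scen[1:2]) {
    ev <- sample_events(sc)$events
    for (pop in sc$populations) {
      k <- sum(ev$truth_class == pop$name)
      ci <- binom_ci99(k, nrow(ev))
      expect_gte(pop$frequency, ci[1])
      expect_lte(pop$frequency, ci[2])
    }
  }
})

test_that("a fixed seed reproduces the event table exactly", {
  sc <- make_scenario("fig2d_capture", n_cells = 500)[[1]]
  a <- sample_events(sc)
  b <- sample_events(sc)
  expect_identical(a, b)
})

test_that("invalid scenarios are rejected with classed errors", {
  pops <- make_scenario("fig2d_capture")[[1]]$populations
  pops[[1]]$frequency <- pops[[1]]$frequency + 0.05
  expect_error(sample_scenario("bad", "EpCAM", pops, 100, 1),
               class = "ctcgate_config_error")
  expect_error(make_scenario("fig9_unknown"),
               class = "ctcgate_lookup_error")
  expect_error(
    sample_scenario("bad", "EpCAM",
                    make_scenario("fig2d_capture")[[1]]$populations, 0, 1),
    class = "ctcgate_validation_error")
  expect_error(population_spec("CTC", 0.5, list(), chan_(4, 1)),
               class = "ctcgate_validation_error")
})
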