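# t tests and the comparison report.

test_that("paired t statistic matches the hand computation", {
  # differences {1,1,2}: mean 4/3, sd 1/sqrt(3) -> t = 4, df = 2
  tt <- ctc_t_test(c(2, 3, 5), c(1, 2, 3), paired = TRUE, tails = 2)
  expect_equal(tt$statistic, 4)
  expect_equal(tt$df, 2)
})

test_that("degenerate and malformed inputs raise classed errors", {
  x <- c(1, 2, 3)
  expect_error(ctc_t_test(x, x, paired = TRUE),
               class = "ctcgate_degenerate_error")
  expect_error(ctc_t_test(x, c(1, 2), paired = TRUE),
               class = "ctcgate_validation_error")
  expect_error(ctc_t_test(c(1), c(1, 2)), class = "ctcgate_validation_error")
})

test_that("t tests agree with the reference implementation to 1e-9", {
  set.seed(77)
  for (rep in 1:100) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    x <- rnorm(n1, mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(n2, mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    ref <- stats::t.test(x, y)
    ours <- ctc_t_test(x, y, paired = FALSE, tails = 2)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
    xp <- rnorm(n1); yp <- rnorm(n1)
    refp <- stats::t.test(xp, yp, paired = TRUE, alternative = "greater")
    oursp <- ctc_t_test(xp, yp, paired = TRUE, tails = 1,
                        direction = "greater")
    expect_equal(oursp$statistic, unname(refp$statistic), tolerance = 1e-9)
    expect_equal(oursp$p_value, refp$p.value, tolerance = 1e-9)
  }
})

test_that("significance is declared strictly below alpha = 0.05", {
  set.seed(11)
  seen <- c(FALSE, FALSE)
  for (rep in 1:200) {
    x <- rnorm(6); y <- rnorm(6)
    tt <- ctc_t_test(x, y)
    expect_identical(tt$significant, tt$p_value < 0.05)
    seen[1 + tt$significant] <- TRUE
  }
  expect_true(all(seen))  # both outcomes exercised
})

test_that("reports list pairwise comparisons deterministically", {
  cap <- run_capture_analysis("fig2e_capture", n_cells = 600, seed = 100)
  rep1 <- build_report(cap$summaries, paired = TRUE, tails = 1,
                       direction = "less")
  rep2 <- build_report(cap$summaries, paired = TRUE, tails = 1,
                       direction = "less")
  expect_identical(rep1, rep2)
  expect_equal(nrow(rep1$tests), 3)
  expect_setequal(paste(rep1$tests$group_a, rep1$tests$group_b),
                  c("EpCAM MUC1", "EpCAM Vim", "MUC1 Vim"))
  # single sample: means only, no tests
  single <- build_report(cap$summaries[1, , drop = FALSE])
  expect_equal(single$n_tests, 0)
  expect_error(build_report(cap$summaries[0, , drop = FALSE]),
               class = "ctcgate_validation_error")
})
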