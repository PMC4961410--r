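#' Build a per-figure comparison report
#'
#' Produces the deterministic tabular report for one figure-level analysis:
#' group means and ranges, pairwise t tests between groups (paired by
#' patient when possible), and star annotations (`*` for p < 0.05). With a
#' single sample no test is run and only the means are reported. No
#' multiple-testing correction is applied; the number of tests performed is
#' recorded so readers can judge the comparisons.
#'
#' @param summaries per-sample summary table (see [summarize_batch()]); a
#'   `patient` column enables paired tests.
#' @param value column under comparison.
#' @param group_key grouping column.
#' @param tails,direction test configuration passed to [ctc_t_test()].
#' @param paired use paired tests (requires a `patient` column).
#' @return list of class `ctc_report`: `groups` (summary table), `tests`
#'   (one row per pairwise comparison, possibly empty), `n_tests`,
#'   `markdown` (character vector of report lines).
#' @export
build_report <- function(summaries, value = "cd11b_fraction",
                         group_key = "capture_antibody", tails = 2,
                         direction = "greater", paired = FALSE) {
  if (!nrow(summaries)) stop_validation("empty batch")
  groups <- sort(unique(summaries[[group_key]]))
  v <- summaries[[value]]
  gtab <- do.call(rbind, lapply(groups, function(k) {
    vk <- v[summaries[[group_key]] == k & !is.na(v)]
    data.frame(group = k, n = length(vk), mean = mean(vk),
               min = min(vk), max = max(vk), stringsAsFactors = FALSE)
  }))
  tests <- data.frame(group_a = character(0), group_b = character(0),
                      t = numeric(0), df = numeric(0), p = numeric(0),
                      stars = character(0), stringsAsFactors = FALSE)
  if (length(groups) >= 2 && nrow(summaries) > length(groups)) {
    combs <- utils::combn(groups, 2, simplify = FALSE)
    for (cb in combs) {
      if (paired) {
        if (!"patient" %in% names(summaries))
          stop_pairing("paired report needs a 'patient' column")
        pa <- summaries[summaries[[group_key]] == cb[1], ]
        pb <- summaries[summaries[[group_key]] == cb[2], ]
        common <- intersect(pa$patient, pb$patient)
        if (length(common) < 2) next
        xa <- pa[[value]][match(common, pa$patient)]
        xb <- pb[[value]][match(common, pb$patient)]
        tt <- ctc_t_test(xa, xb, paired = TRUE, tails = tails,
                         direction = direction)
      } else {
        xa <- v[summaries[[group_key]] == cb[1] & !is.na(v)]
        xb <- v[summaries[[group_key]] == cb[2] & !is.na(v)]
        if (length(xa) < 2 || length(xb) < 2) next
        tt <- ctc_t_test(xa, xb, paired = FALSE, tails = tails,
                         direction = direction)
      }
      tests <- rbind(tests, data.frame(
        group_a = cb[1], group_b = cb[2], t = tt$statistic, df = tt$df,
        p = tt$p_value, stars = if (tt$significant) "*" else "",
        stringsAsFactors = FALSE))
    }
  }
  md <- c(sprintf("# Comparison of %s by %s", value, group_key), "",
          "| group | n | mean | min | max |",
          "|---|---|---|---|---|",
          sprintf("| %s | %d | %.4f | %.4f | %.4f |",
                  gtab$group, gtab$n, gtab$mean, gtab$min, gtab$max))
  if (nrow(tests)) {
    md <- c(md, "",
            sprintf("%d pairwise t test(s), no multiple-testing correction:",
                    nrow(tests)),
            "",
            "| A | B | t | df | p | |",
            "|---|---|---|---|---|---|",
            sprintf("| %s | %s | %.4f | %.2f | %.4g | %s |",
                    tests$group_a, tests$group_b, tests$t, tests$df,
                    tests$p, tests$stars))
  }
  structure(list(groups = gtab, tests = tests, n_tests = nrow(tests),
                 markdown = md),
            class = "ctc_report")
}

#' Write a report to Markdown and CSV files
#'
#' @param report a [build_report()] result.
#' @param path_md,path_csv output file paths (either may be `NULL`).
#' @return invisibly, the report.
#' @export
write_report <- function(report, path_md = NULL, path_csv = NULL) {
  if (!is.null(path_md)) writeLines(report$markdown, path_md)
  if (!is.null(path_csv)) {
    tab <- report$groups
    write.csv(tab, path_csv, row.names = FALSE)
  }
  invisible(report)
}
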