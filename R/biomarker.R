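#' Fraction of standard-identified CTCs that are myeloid false positives
#'
#' `n(MYELOID_FP) / n(CTC_standard)` where the standard pool is the union of
#' strict CTCs and myeloid false positives. Undefined (flagged, not zero)
#' when no event met the standard CTC definition.
#'
#' @param labels strict classification labels (from [classify_strict()] or
#'   the `class_label` column of [classify_batch()]).
#' @return fraction in `[0, 1]`, or [flagged_na()].
#' @export
false_positive_fraction <- function(labels) {
  if (!length(labels)) stop_validation("no labels supplied")
  n_fp <- sum(labels == "MYELOID_FP")
  n_std <- n_fp + sum(labels == "CTC_strict")
  if (n_std == 0) return(flagged_na("no standard-identified CTCs"))
  n_fp / n_std
}

#' Fraction of all captured events that are CD11b-positive
#'
#' @param events event table with a `CD11b` column.
#' @param cd11b_cutoff CD11b positivity cutoff.
#' @return fraction in `[0, 1]`, or [flagged_na()] for an empty table.
#' @export
cd11b_fraction <- function(events, cd11b_cutoff) {
  if (!is.finite(cd11b_cutoff)) stop_config("CD11b cutoff must be finite")
  if (!nrow(events)) return(flagged_na("empty event table"))
  mean(events$CD11b >= cd11b_cutoff)
}

#' Ratio of mean channel MFI between two event groups
#'
#' @param events event table.
#' @param labels per-event group labels (same length as `events` rows).
#' @param group_a,group_b labels of the numerator and denominator groups.
#' @param channel channel column to compare.
#' @return `mean(channel | group_a) / mean(channel | group_b)`, or
#'   [flagged_na()] when either group is empty or the denominator mean is 0.
#' @export
population_fold_change <- function(events, labels, group_a, group_b, channel) {
  if (length(labels) != nrow(events))
    stop_validation("labels must match the event table")
  a <- events[[channel]][labels == group_a]
  b <- events[[channel]][labels == group_b]
  if (!length(a) || !length(b))
    return(flagged_na("empty comparison group"))
  mb <- mean(b)
  if (mb == 0) return(flagged_na("zero denominator mean"))
  mean(a) / mb
}

#' Per-sample biomarker summary under standard and strict CTC criteria
#'
#' Computes, side by side, the quantities that differ between the two CTC
#' definitions: event counts, the false-positive fraction, mean PD-L1 MFI
#' over each CTC set, and the fraction of each CTC set at or above the
#' PD-L1 positivity cutoff. Arithmetic means are used for MFI.
#'
#' @param events event table for one sample with a `class_label` column.
#' @param pdl1_cutoff PD-L1 positivity cutoff (intensity units).
#' @param cd11b_cutoff CD11b cutoff used for the whole-sample CD11b+
#'   fraction (optional; `NA` skips it).
#' @return one-row data.frame of class `biomarker_summary` with columns
#'   `sample_id`, `capture_antibody`, `n_events`, `n_ctc_standard`,
#'   `n_ctc_strict`, `n_myeloid_fp`, `cd11b_fraction`, `fp_fraction`,
#'   `pdl1_mfi_standard`, `pdl1_mfi_strict`, `pdl1_pos_freq_standard`,
#'   `pdl1_pos_freq_strict`. Undefined entries are `NA` (flagged upstream),
#'   never silent zeros.
#' @export
pdl1_summary <- function(events, pdl1_cutoff, cd11b_cutoff = NA_real_) {
  if (!"class_label" %in% names(events))
    stop_validation("events must carry strict classification labels")
  if (!nrow(events)) stop_validation("empty event table")
  lab <- events$class_label
  strict <- lab == "CTC_strict"
  fp <- lab == "MYELOID_FP"
  std <- strict | fp
  pd <- events$PDL1
  mfi <- function(sel) if (any(sel)) mean(pd[sel]) else NA_real_
  pos <- function(sel) if (any(sel)) mean(pd[sel] >= pdl1_cutoff) else NA_real_
  out <- data.frame(
    sample_id = events$sample_id[1],
    capture_antibody = events$capture_antibody[1],
    n_events = nrow(events),
    n_ctc_standard = sum(std),
    n_ctc_strict = sum(strict),
    n_myeloid_fp = sum(fp),
    cd11b_fraction = if (is.finite(cd11b_cutoff))
      as.numeric(cd11b_fraction(events, cd11b_cutoff)) else NA_real_,
    fp_fraction = as.numeric(false_positive_fraction(lab)),
    pdl1_mfi_standard = mfi(std),
    pdl1_mfi_strict = mfi(strict),
    pdl1_pos_freq_standard = pos(std),
    pdl1_pos_freq_strict = pos(strict),
    stringsAsFactors = FALSE)
  class(out) <- c("biomarker_summary", class(out))
  out
}

#' Summarize every sample of a classified batch
#'
#' @param events stacked classified event table (from [classify_batch()]).
#' @param pdl1_cutoff,cd11b_cutoff positivity cutoffs; by default taken from
#'   the batch's `thresholds` attribute.
#' @return data.frame with one [pdl1_summary()] row per sample, in order of
#'   first appearance.
#' @export
summarize_batch <- function(events, pdl1_cutoff = NULL, cd11b_cutoff = NULL) {
  th <- attr(events, "thresholds")
  if (is.null(pdl1_cutoff)) pdl1_cutoff <- th$cutoffs[["PDL1"]]
  if (is.null(cd11b_cutoff))
    cd11b_cutoff <- if ("CD11b" %in% names(th$cutoffs))
      th$cutoffs[["CD11b"]] else NA_real_
  ids <- unique(events$sample_id)
  out <- do.call(rbind, lapply(ids, function(id)
    pdl1_summary(events[events$sample_id == id, , drop = FALSE],
                 pdl1_cutoff = pdl1_cutoff, cd11b_cutoff = cd11b_cutoff)))
  rownames(out) <- NULL
  out
}

#' Compare biomarker summaries across groups
#'
#' Groups per-sample summaries by a key (typically `capture_antibody`),
#' reports each group's mean and range for a chosen quantity, and — when
#' samples pair across groups (same patients measured under each condition)
#' — aligns the paired values for downstream testing.
#'
#' @param summaries data.frame of [pdl1_summary()] rows, plus a `patient`
#'   column when pairing is requested.
#' @param group_key grouping column (default `capture_antibody`).
#' @param value column to compare (default `cd11b_fraction`).
#' @param paired require pairing by `patient` across groups.
#' @return list of class `batch_comparison`: `table` (group, n, mean, min,
#'   max) and, when paired, `pairs` (patient-by-group value matrix).
#' @export
batch_compare <- function(summaries, group_key = "capture_antibody",
                          value = "cd11b_fraction", paired = FALSE) {
  if (nrow(summaries) < 2) stop_validation("need at least two summaries")
  g <- summaries[[group_key]]
  v <- summaries[[value]]
  tab <- do.call(rbind, lapply(unique(g), function(k) {
    vk <- v[g == k & !is.na(v)]
    data.frame(group = k, n = length(vk), mean = mean(vk),
               min = min(vk), max = max(vk), stringsAsFactors = FALSE)
  }))
  pairs <- NULL
  if (paired) {
    if (!"patient" %in% names(summaries))
      stop_pairing("paired comparison needs a 'patient' column")
    wide <- tapply(v, list(summaries$patient, g), function(x) x[1])
    if (any(is.na(wide)))
      stop_pairing("sample sets do not pair across groups")
    pairs <- wide
  }
  structure(list(table = tab, pairs = pairs, value = value),
            class = "batch_comparison")
}
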