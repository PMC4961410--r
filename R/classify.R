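#' Classify events by the standard CTC definition (pCK+ CD45-)
#'
#' The traditional criterion: an event is a standard CTC when pCK is at or
#' above its cutoff and CD45 below its cutoff; events at or above the CD45
#' cutoff are WBCs; everything else is OTHER. CD45-low and CD45-negative
#' events are deliberately not distinguished — both fall below the CD45
#' cutoff, which is what lets CD45-low myeloid cells through.
#'
#' @param events event table with `pCK` and `CD45` columns.
#' @param thresholds a [derive_thresholds()] `threshold_set` with `pCK` and
#'   `CD45` cutoffs.
#' @return character vector of labels `CTC_standard` / `WBC` / `OTHER`.
#' @export
classify_standard <- function(events, thresholds) {
  cut <- thresholds$cutoffs
  if (!all(c("pCK", "CD45") %in% names(cut)) ||
      any(!is.finite(cut[c("pCK", "CD45")])))
    stop_config("classify_standard needs finite pCK and CD45 cutoffs")
  labels <- rep("OTHER", nrow(events))
  labels[events$CD45 >= cut["CD45"]] <- "WBC"
  labels[events$CD45 < cut["CD45"] & events$pCK >= cut["pCK"]] <- "CTC_standard"
  labels
}

#' Classify events with the strict (CD11b-exclusion) CTC definition
#'
#' Starts from [classify_standard()], then relabels standard CTCs that are
#' CD11b-positive as `MYELOID_FP` (myeloid false positives); the remaining
#' standard CTCs become `CTC_strict`. By construction the strict set is a
#' subset of the standard set and `MYELOID_FP` is exactly their difference.
#'
#' @param events event table with `pCK`, `CD45` and `CD11b` columns.
#' @param thresholds `threshold_set` with `pCK`, `CD45` and `CD11b` cutoffs.
#' @return character vector of labels
#'   `CTC_strict` / `MYELOID_FP` / `WBC` / `OTHER`.
#' @export
classify_strict <- function(events, thresholds) {
  cut <- thresholds$cutoffs
  if (!"CD11b" %in% names(cut) || !is.finite(cut["CD11b"]))
    stop_config("classify_strict needs a finite CD11b cutoff")
  labels <- classify_standard(events, thresholds)
  std <- labels == "CTC_standard"
  labels[std & events$CD11b >= cut["CD11b"]] <- "MYELOID_FP"
  labels[std & events$CD11b < cut["CD11b"]] <- "CTC_strict"
  labels
}

#' Classify a batch of samples with uniformly applied thresholds
#'
#' Derives cutoffs on the representative sample (by default the first
#' sample of the batch) and applies them verbatim to every sample,
#' mirroring thresholds set once on a representative specimen and reused
#' across a batch acquired under the same conditions.
#'
#' @param events stacked event table of several samples (`sample_id`
#'   column).
#' @param channels channels to derive cutoffs for.
#' @param representative sample id to derive thresholds on; default the
#'   first sample in the table.
#' @param manual named manual cutoff overrides (see [derive_thresholds()]).
#' @return `events` with a `class_label` column (strict classification) and
#'   attribute `thresholds` (the `threshold_set` used).
#' @export
classify_batch <- function(events, channels = c("CD45", "CD11b", "pCK", "PDL1"),
                           representative = NULL, manual = NULL) {
  if (!nrow(events)) stop_validation("empty event table")
  rep_id <- if (is.null(representative)) events$sample_id[1] else representative
  rep_ev <- events[events$sample_id == rep_id, , drop = FALSE]
  if (!nrow(rep_ev))
    stop_lookup(sprintf("representative sample '%s' not in table", rep_id))
  th <- derive_thresholds(rep_ev, channels = channels, manual = manual)
  events$class_label <- classify_strict(events, th)
  attr(events, "thresholds") <- th
  events
}
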