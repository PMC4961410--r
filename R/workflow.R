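# Figure-level workflows. Each function runs one complete analysis the way
# the drivers under analysis/ do: simulate (event table or rendered tiles),
# process, derive thresholds on the representative sample, classify, and
# summarize. The acceptance script and tests call these, so the numbers in
# results/ always come from the same code path.

#' Simulate a preset in event mode
#'
#' @param preset preset name (see [make_scenario()]).
#' @param n_cells cells per sample (`NULL` for the preset default).
#' @param seed base seed.
#' @return list: `scenarios`, `events` (stacked table with truth labels),
#'   `truth` (list of per-sample truth tables).
#' @export
simulate_preset <- function(preset, n_cells = NULL, seed = 100) {
  scenarios <- make_scenario(preset, n_cells = n_cells, seed = seed)
  drawn <- lapply(scenarios, sample_events)
  events <- do.call(rbind, lapply(drawn, `[[`, "events"))
  rownames(events) <- NULL
  list(scenarios = scenarios, events = events,
       truth = lapply(drawn, `[[`, "truth"))
}

# gate labels for the buffy-coat comparison: CD11b+ cells versus
# CD11b- CD45- comparators (CD45-depleted input, so the CD11b axis defines
# the myeloid gate and the CD45 cutoff only cleans the comparator)
label_myeloid_comparator <- function(events, thresholds) {
  cut <- thresholds$cutoffs
  lab <- rep("UNGATED", nrow(events))
  lab[events$CD11b >= cut["CD11b"]] <- "MYELOID_GATE"
  lab[events$CD11b < cut["CD11b"] & events$CD45 < cut["CD45"]] <- "COMPARATOR"
  lab
}

#' Non-specific staining fold-change analysis (buffy-coat comparison)
#'
#' Recovers, per simulated patient, the ratio of mean pCK (and isotype) MFI
#' between gated CD11b+ CD45-low cells and CD11b- CD45- comparators.
#' Thresholds are derived on the first sample and applied uniformly.
#'
#' @param events stacked event table from [simulate_preset()] (`fig1_flow`).
#' @param channels channels to compute fold-changes for.
#' @return data.frame: `sample_id`, one `ratio_<channel>` column per channel.
#' @export
analyze_fold_changes <- function(events, channels = c("pCK", "isotype")) {
  rep_ev <- events[events$sample_id == events$sample_id[1], , drop = FALSE]
  th <- derive_thresholds(rep_ev, channels = c("CD45", "CD11b"))
  ids <- unique(events$sample_id)
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (ch in channels) out[[paste0("ratio_", ch)]] <- NA_real_
  for (i in seq_along(ids)) {
    ev <- events[events$sample_id == ids[i], , drop = FALSE]
    lab <- label_myeloid_comparator(ev, th)
    for (ch in channels)
      out[[paste0("ratio_", ch)]][i] <- as.numeric(
        population_fold_change(ev, lab, "MYELOID_GATE", "COMPARATOR", ch))
  }
  out
}

#' Capture-antibody contamination analysis (event mode)
#'
#' Simulates a capture preset, classifies the batch with thresholds from the
#' representative sample, and reports the per-sample summaries (CD11b+
#' fraction of all captured events, false-positive fraction, PD-L1 columns).
#'
#' @param preset preset name.
#' @param n_cells cells per sample (`NULL` for the preset default).
#' @param seed base seed.
#' @return list: `events` (classified), `summaries` (one row per sample with
#'   added `patient` and `capture_antibody` columns), `thresholds`.
#' @export
run_capture_analysis <- function(preset, n_cells = NULL, seed = 100) {
  sim <- simulate_preset(preset, n_cells = n_cells, seed = seed)
  classified <- classify_batch(sim$events)
  summaries <- summarize_batch(classified)
  summaries$patient <- sub("_(EpCAM|MUC1|Vim)$", "", summaries$sample_id)
  list(events = classified, summaries = summaries,
       thresholds = attr(classified, "thresholds"),
       scenarios = sim$scenarios)
}

#' Capture-antibody contamination analysis through the image pipeline
#'
#' Renders each scenario of a preset into noisy overlapping tiles, runs the
#' full image pipeline (stitch, subtract background, segment nuclei with
#' touching-cell splitting, measure MFIs), then classifies and summarizes
#' exactly as the event-mode analysis does.
#'
#' @param preset preset name.
#' @param n_cells cells per sample.
#' @param seed base seed (placement/noise streams are derived per sample).
#' @param img an [image_params()] object.
#' @param pp a [pipeline_params()] object.
#' @return list: `events` (classified, with matched `truth_class`),
#'   `summaries`, `thresholds`, `rendered` (per-sample event counts and
#'   background estimates as provenance).
#' @export
run_image_analysis <- function(preset, n_cells = NULL, seed = 100,
                               img = image_params(), pp = pipeline_params()) {
  scenarios <- make_scenario(preset, n_cells = n_cells, seed = seed)
  all_events <- list()
  prov <- list()
  for (sc in scenarios) {
    drawn <- sample_events(sc)
    rend <- render_sample(drawn$events, params = img, seed = sc$seed)
    ev <- run_image_pipeline(rend$grid, params = pp,
                             sample_id = sc$sample_id,
                             capture_antibody = sc$capture_antibody)
    ev <- match_truth(ev, rend$truth$events)
    all_events[[sc$sample_id]] <- ev
    prov[[sc$sample_id]] <- list(n_planted = nrow(drawn$events),
                                 n_measured = nrow(ev),
                                 background = attr(ev, "background"))
  }
  events <- do.call(rbind, all_events)
  rownames(events) <- NULL
  classified <- classify_batch(events)
  summaries <- summarize_batch(classified)
  summaries$patient <- sub("_(EpCAM|MUC1|Vim)$", "", summaries$sample_id)
  list(events = classified, summaries = summaries,
       thresholds = attr(classified, "thresholds"), rendered = prov)
}
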