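#' Draw a per-cell event table from a scenario
#'
#' Emulates the flow-cytometry readout: population membership is drawn
#' multinomially from the planted frequencies and each marker intensity is
#' drawn from the member population's log-normal. Cell radii (used only by
#' the image renderer) are drawn here too, from a dedicated random
#' sub-stream, so event-mode and image-mode intensities of the same scenario
#' are identical.
#'
#' @param scenario a [sample_scenario()].
#' @return list with elements
#'   \describe{
#'     \item{events}{data.frame with `sample_id`, `capture_antibody`,
#'       `event_id`, one MFI column per channel in [CTC_CHANNELS], `radius`
#'       and `truth_class`.}
#'     \item{truth}{data.frame with `event_id`, `truth_class` and the
#'       planted per-channel arithmetic means of the member population
#'       (columns `mean_<channel>`).}
#'   }
#' @export
sample_events <- function(scenario) {
  if (!inherits(scenario, "sample_scenario"))
    stop_validation("scenario must be a sample_scenario")
  freqs <- vapply(scenario$populations, `[[`, numeric(1), "frequency")
  if (abs(sum(freqs) - 1) > 1e-9)
    stop_config("population frequencies must sum to 1")
  n <- scenario$n_cells
  if (n < 1) stop_validation("n_cells must be >= 1")

  set.seed(derive_seed(scenario$seed, "membership"))
  member <- sample.int(length(freqs), n, replace = TRUE, prob = freqs)

  set.seed(derive_seed(scenario$seed, "intensity"))
  intens <- matrix(NA_real_, n, length(CTC_CHANNELS),
                   dimnames = list(NULL, CTC_CHANNELS))
  for (ch in CTC_CHANNELS) {
    for (k in seq_along(scenario$populations)) {
      idx <- which(member == k)
      if (!length(idx)) next
      p <- scenario$populations[[k]]$channels[[ch]]
      # gsd 1 is a point mass at the median (no exp/log round trip)
      intens[idx, ch] <- if (p[["gsd"]] == 1) p[["median"]] else
        rlnorm(length(idx), log(p[["median"]]), log(p[["gsd"]]))
    }
  }

  set.seed(derive_seed(scenario$seed, "size"))
  radius <- numeric(n)
  for (k in seq_along(scenario$populations)) {
    idx <- which(member == k)
    if (!length(idx)) next
    p <- scenario$populations[[k]]$radius
    r <- if (p[["gsd"]] == 1) rep(p[["median"]], length(idx)) else
      rlnorm(length(idx), log(p[["median"]]), log(p[["gsd"]]))
    radius[idx] <- pmax(r, 2)
  }

  classes <- vapply(scenario$populations, `[[`, character(1), "truth_class")
  events <- data.frame(sample_id = scenario$sample_id,
                       capture_antibody = scenario$capture_antibody,
                       event_id = seq_len(n),
                       intens,
                       radius = radius,
                       truth_class = classes[member],
                       stringsAsFactors = FALSE)

  means <- t(vapply(scenario$populations, function(p)
    vapply(p$channels, lnorm_mean, numeric(1)),
    numeric(length(CTC_CHANNELS))))
  truth <- data.frame(event_id = seq_len(n), truth_class = classes[member],
                      means[member, , drop = FALSE])
  names(truth)[-(1:2)] <- paste0("mean_", CTC_CHANNELS)
  list(events = events, truth = truth)
}

#' Draw event tables for every scenario of a preset
#'
#' @param scenarios a list of scenarios from [make_scenario()].
#' @return a single data.frame of all events, rows stacked in scenario order.
#' @export
sample_events_batch <- function(scenarios) {
  do.call(rbind, lapply(scenarios, function(s) sample_events(s)$events))
}
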