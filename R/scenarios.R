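#' Define a planted cell population
#'
#' A population is a cell class with a frequency and, per marker channel, a
#' log-normal intensity distribution parameterized by its median and
#' geometric standard deviation (GSD) in arbitrary fluorescence units.
#' Log-normals are the conventional model for fluorescence intensities:
#' strictly positive and right-skewed. Cell radius (pixels) follows the same
#' parameterization.
#'
#' @param name population label, one of `WBC`, `MYELOID`, `CTC`, `OTHER`.
#' @param frequency expected fraction of the sample in `[0, 1]`.
#' @param channels named list; one `c(median = , gsd = )` entry per channel
#'   in [CTC_CHANNELS]. `gsd` must be `>= 1` (a GSD of 1 is a point mass,
#'   used by degenerate test scenarios).
#' @param radius `c(median = , gsd = )` for the nuclear radius in pixels;
#'   median must be at least 2.
#' @param truth_class ground-truth label attached to every simulated cell;
#'   defaults to `name`.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(name, frequency, channels, radius,
                            truth_class = name) {
  if (!name %in% CTC_CLASSES)
    stop_validation(sprintf("unknown population name '%s'", name))
  if (!is.numeric(frequency) || frequency < 0 || frequency > 1)
    stop_validation("frequency must lie in [0, 1]")
  missing_ch <- setdiff(CTC_CHANNELS, names(channels))
  if (length(missing_ch))
    stop_validation(paste("missing channel parameters:",
                          paste(missing_ch, collapse = ", ")))
  for (ch in names(channels)) {
    p <- channels[[ch]]
    if (!all(c("median", "gsd") %in% names(p)))
      stop_validation(sprintf("channel '%s' needs median and gsd", ch))
    if (p[["median"]] <= 0 || p[["gsd"]] < 1)
      stop_validation(sprintf("channel '%s': median must be > 0, gsd >= 1", ch))
  }
  if (radius[["median"]] < 2)
    stop_validation("radius median must be >= 2 pixels")
  structure(list(name = name, frequency = frequency,
                 channels = channels[CTC_CHANNELS], radius = radius,
                 truth_class = truth_class),
            class = "population_spec")
}

#' Define a simulated sample
#'
#' A scenario fixes everything needed to draw one sample: the capture
#' antibody (which determines the mixture composition), the planted
#' populations, the number of cells, and the random seed. Population
#' frequencies must sum to 1.
#'
#' @param sample_id sample identifier.
#' @param capture_antibody one of `EpCAM`, `MUC1`, `Vim`.
#' @param populations list of [population_spec()] objects.
#' @param n_cells number of cells to draw (at least 1).
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return an object of class `sample_scenario` whose `planted` element
#'   records the scenario's analytically known summaries
#'   (see [planted_summaries()]).
#' @export
sample_scenario <- function(sample_id, capture_antibody, populations,
                            n_cells, seed) {
  if (!capture_antibody %in% c("EpCAM", "MUC1", "Vim"))
    stop_validation("capture_antibody must be EpCAM, MUC1 or Vim")
  if (!is.numeric(n_cells) || n_cells < 1)
    stop_validation("n_cells must be a positive integer")
  freqs <- vapply(populations, `[[`, numeric(1), "frequency")
  if (abs(sum(freqs) - 1) > 1e-9)
    stop_config(sprintf("population frequencies sum to %.12f, not 1",
                        sum(freqs)))
  sc <- structure(list(sample_id = sample_id,
                       capture_antibody = capture_antibody,
                       populations = populations,
                       n_cells = as.integer(n_cells),
                       seed = as.integer(seed)),
                  class = "sample_scenario")
  sc$planted <- planted_summaries(sc)
  sc
}

# meanlog/sdlog of the log-normal given median and geometric SD
lnorm_pars <- function(p) list(meanlog = log(p[["median"]]),
                               sdlog = log(p[["gsd"]]))

#' Arithmetic mean of a median/GSD log-normal
#'
#' `median * exp(log(gsd)^2 / 2)`; used to relate planted medians to the
#' arithmetic-mean MFIs the pipeline measures.
#'
#' @param p a `c(median = , gsd = )` parameter vector.
#' @return the distribution's arithmetic mean.
#' @export
lnorm_mean <- function(p) p[["median"]] * exp(log(p[["gsd"]])^2 / 2)

#' Analytically known summaries of a scenario
#'
#' Recomputes, from the population parameters alone, the quantities the
#' pipeline is later asked to recover: the myeloid contamination fraction,
#' the per-class marker means, the MYELOID:OTHER (or MYELOID:CTC-comparator)
#' pCK and isotype mean ratios, and the contamination of the pCK+CD45-
#' standard CTC pool. Stored on the scenario at construction and
#' re-derivable at any time, so self-consistency is checkable.
#'
#' @param scenario a [sample_scenario()] (the `planted` element is ignored).
#' @return list with elements `frequencies`, `class_means`,
#'   `contamination_fraction`, `fp_fraction_standard`, `pck_ratio`,
#'   `isotype_ratio`, `pdl1_mean`.
#' @export
planted_summaries <- function(scenario) {
  pops <- scenario$populations
  nm <- vapply(pops, `[[`, character(1), "name")
  freq <- setNames(vapply(pops, `[[`, numeric(1), "frequency"), nm)
  class_means <- sapply(pops, function(p)
    vapply(p$channels, lnorm_mean, numeric(1)))
  colnames(class_means) <- nm
  frac <- function(x) if (length(x)) sum(x) else 0
  myeloid <- frac(freq[nm == "MYELOID"])
  ctc <- frac(freq[nm == "CTC"])
  ratio_to <- function(channel, ref_class) {
    if (!"MYELOID" %in% nm || !ref_class %in% nm) return(NA_real_)
    class_means[channel, "MYELOID"] / class_means[channel, ref_class]
  }
  ref <- if ("OTHER" %in% nm) "OTHER" else if ("CTC" %in% nm) "CTC" else NA
  list(
    frequencies = freq,
    class_means = class_means,
    contamination_fraction = myeloid,
    fp_fraction_standard = if (myeloid + ctc > 0) myeloid / (myeloid + ctc)
                           else NA_real_,
    pck_ratio = if (is.na(ref)) NA_real_ else ratio_to("pCK", ref),
    isotype_ratio = if (is.na(ref)) NA_real_ else ratio_to("isotype", ref),
    pdl1_mean = class_means["PDL1", , drop = TRUE]
  )
}

#' Check a scenario's stored planted summaries against its parameters
#'
#' @param scenario a [sample_scenario()].
#' @param tol numeric tolerance (default `1e-9`).
#' @return `TRUE` invisibly; errors if any stored summary disagrees with the
#'   value recomputed from the population parameters.
#' @export
check_scenario <- function(scenario, tol = 1e-9) {
  fresh <- planted_summaries(scenario)
  stored <- scenario$planted
  cmp <- function(a, b) {
    both_na <- all(is.na(a)) && all(is.na(b))
    both_na || isTRUE(all.equal(a, b, tolerance = tol))
  }
  for (k in names(fresh)) {
    if (!cmp(fresh[[k]], stored[[k]]))
      stop_validation(sprintf("planted summary '%s' is not self-consistent", k))
  }
  invisible(TRUE)
}
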