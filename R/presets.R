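# Scenario presets. Each preset plants, as ground truth, the per-figure
# summary statistics the study reports, so running the full pipeline over a
# preset and recovering those numbers exercises every stage end to end.
#
# Planted vectors (see the methods vignette for the construction rule):
#   fig1_flow      pCK MFI ratios MYELOID:comparator {8, 9, 22}  (mean 13)
#                  isotype ratios {12, 19, 38}                   (mean 23)
#   fig2d_capture  MYELOID frequency by capture antibody
#                  EpCAM 0.22, MUC1 0.27, Vim 0.47
#   fig2e_capture  per-patient MYELOID frequency (5 patients):
#                  EpCAM {.05,.10,.18,.25,.32}   (mean 0.18)
#                  MUC1  {.10,.06,.25,.34,.25}   (mean 0.20)
#                  Vim   {.03,.30,.45,.61,.66}   (mean 0.41)
#                  The per-patient EpCAM/MUC1 values are constrained choices
#                  (only the means and the overall 3-66% range are known).
#   fig3_falsepos  contamination of the standard pCK+CD45- CTC pool:
#                  EpCAM {.33,.71,1.00,1.00} (mean 0.76)
#                  MUC1  {.33,.63,1.00,1.00} (mean 0.74; endpoints from the
#                  reported range, middle value forced by the mean)
#   fig4_pdl1      7 MUC1 patients, contamination {.2,...,.8}, per-patient
#                  CTC PD-L1 medians {25,40,60,80,120,50,30}; MYELOID PD-L1
#                  median 250 (synthetic choices; no per-patient values are
#                  reported)
#   s1_muc1        false-positive fractions {.10,.12,.10,.20} (mean 0.13)

# Baseline marker intensities (arbitrary fluorescence units). Medians are
# separated by >= 1 decade on every gated axis so density-valley thresholds
# are well defined; GSDs are typical of immunofluorescence (1.6-1.8).
chan <- function(median, gsd) c(median = median, gsd = gsd)

base_channels <- function() list(
  Hoechst = chan(20000, 1.3),
  CD45    = chan(40, 1.6),
  CD11b   = chan(30, 1.6),
  pCK     = chan(10, 1.8),
  PDL1    = chan(30, 1.8),
  isotype = chan(8, 1.8),
  capture = chan(50, 1.8)
)

wbc_population <- function(frequency) {
  ch <- base_channels()
  ch$CD45 <- chan(5000, 1.6)
  population_spec("WBC", frequency, ch, radius = chan(5, 1.15))
}

# CD45-low, CD11b-high, granulocyte-sized; pCK and isotype medians are the
# baseline scaled by the planted non-specific staining fold-changes.
myeloid_population <- function(frequency, pck_ratio = 12, isotype_ratio = 23,
                               pdl1 = chan(250, 1.8)) {
  ch <- base_channels()
  ch$CD45 <- chan(250, 1.6)
  ch$CD11b <- chan(3000, 1.6)
  ch$pCK <- chan(10 * pck_ratio, 1.8)
  ch$isotype <- chan(8 * isotype_ratio, 1.8)
  ch$PDL1 <- pdl1
  ch$capture <- chan(300, 1.8)
  population_spec("MYELOID", frequency, ch, radius = chan(7, 1.15))
}

ctc_population <- function(frequency, pdl1 = chan(60, 1.8)) {
  ch <- base_channels()
  ch$pCK <- chan(150, 1.8)
  ch$PDL1 <- pdl1
  ch$capture <- chan(800, 1.8)
  population_spec("CTC", frequency, ch, radius = chan(8, 1.15))
}

# CD45- CD11b- pCK- comparator population (CD45-depleted buffy coat)
other_population <- function(frequency) {
  population_spec("OTHER", frequency, base_channels(), radius = chan(5, 1.15))
}

# capture mixtures: myeloid fraction f; the rest split 80/20 WBC/CTC
capture_mix <- function(f, ...) list(
  wbc_population(0.8 * (1 - f)),
  myeloid_population(f, ...),
  ctc_population(0.2 * (1 - f))
)

# standard-CTC pool contamination c: pool is 40% of the sample, WBC the rest
contamination_mix <- function(c, ctc_pdl1 = chan(60, 1.8),
                              myeloid_pdl1 = chan(250, 1.8)) {
  pops <- list(wbc_population(0.6))
  if (c > 0) pops <- c(pops, list(myeloid_population(0.4 * c,
                                                     pdl1 = myeloid_pdl1)))
  if (c < 1) pops <- c(pops, list(ctc_population(0.4 * (1 - c),
                                                 pdl1 = ctc_pdl1)))
  pops
}

PRESET_NAMES <- c("fig1_flow", "fig2d_capture", "fig2e_capture",
                  "fig3_falsepos", "fig4_pdl1", "s1_muc1")

#' Build the scenarios of a named study preset
#'
#' Each preset encodes one figure-level experiment as a set of fully
#' parameterized [sample_scenario()] objects whose planted truths are the
#' study's printed summary statistics (see the preset table in this file and
#' the methods vignette).
#'
#' @param preset_name one of `fig1_flow`, `fig2d_capture`, `fig2e_capture`,
#'   `fig3_falsepos`, `fig4_pdl1`, `s1_muc1`.
#' @param n_cells cells per sample; defaults to 5000 for `fig1_flow` and
#'   2000 otherwise.
#' @param seed base seed; scenario `i` uses `seed + i`. Default 100.
#' @return a named list of `sample_scenario` objects with attribute `preset`.
#' @export
make_scenario <- function(preset_name, n_cells = NULL, seed = 100) {
  if (!preset_name %in% PRESET_NAMES)
    stop_lookup(sprintf("unknown preset '%s' (known: %s)", preset_name,
                        paste(PRESET_NAMES, collapse = ", ")))
  n <- if (is.null(n_cells)) {
    if (preset_name == "fig1_flow") 5000L else 2000L
  } else as.integer(n_cells)

  scen <- switch(preset_name,
    fig1_flow = {
      pck <- c(8, 9, 22); iso <- c(12, 19, 38)
      lapply(1:3, function(i) sample_scenario(
        sprintf("fig1_patient%d", i), "EpCAM",
        list(wbc_population(0.15),
             myeloid_population(0.35, pck_ratio = pck[i],
                                isotype_ratio = iso[i]),
             other_population(0.50)),
        n_cells = n, seed = seed + i))
    },
    fig2d_capture = {
      f <- c(EpCAM = 0.22, MUC1 = 0.27, Vim = 0.47)
      lapply(seq_along(f), function(i) sample_scenario(
        sprintf("fig2d_%s", names(f)[i]), names(f)[i],
        capture_mix(f[[i]]), n_cells = n, seed = seed + i))
    },
    fig2e_capture = {
      f <- list(EpCAM = c(.05, .10, .18, .25, .32),
                MUC1  = c(.10, .06, .25, .34, .25),
                Vim   = c(.03, .30, .45, .61, .66))
      out <- list()
      for (pat in 1:5) for (ab in names(f)) {
        out[[length(out) + 1L]] <- sample_scenario(
          sprintf("fig2e_patient%d_%s", pat, ab), ab,
          capture_mix(f[[ab]][pat]), n_cells = n,
          seed = seed + 10 * pat + match(ab, names(f)))
      }
      out
    },
    fig3_falsepos = {
      cc <- list(EpCAM = c(.33, .71, 1, 1), MUC1 = c(.33, .63, 1, 1))
      out <- list()
      for (pat in 1:4) for (ab in names(cc)) {
        out[[length(out) + 1L]] <- sample_scenario(
          sprintf("fig3_patient%d_%s", pat, ab), ab,
          contamination_mix(cc[[ab]][pat]), n_cells = n,
          seed = seed + 10 * pat + match(ab, names(cc)))
      }
      out
    },
    fig4_pdl1 = {
      cc <- c(.2, .3, .4, .5, .6, .7, .8)
      pdl1 <- c(25, 40, 60, 80, 120, 50, 30)
      lapply(seq_along(cc), function(i) sample_scenario(
        sprintf("fig4_patient%d", i), "MUC1",
        contamination_mix(cc[i], ctc_pdl1 = chan(pdl1[i], 1.8)),
        n_cells = n, seed = seed + i))
    },
    s1_muc1 = {
      fp <- c(.10, .12, .10, .20)
      lapply(seq_along(fp), function(i) sample_scenario(
        sprintf("s1_patient%d", i), "MUC1",
        contamination_mix(fp[i]), n_cells = n, seed = seed + i))
    })

  names(scen) <- vapply(scen, `[[`, character(1), "sample_id")
  structure(scen, preset = preset_name)
}
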