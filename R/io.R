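#' Write a tile grid as multi-page 16-bit TIFFs with a JSON layout sidecar
#'
#' One TIFF per tile (one page per channel, in [CTC_CHANNELS] order) plus
#' `layout.json` recording per-tile grid position, 0-based pixel offsets,
#' tile sizes, channel names and bit depth.
#'
#' @param grid a [tile_grid()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_tile_grid <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  top <- 2^grid$bit_depth - 1
  paths <- character(0)
  for (t in seq_len(nrow(grid$layout))) {
    arr <- grid$tiles[[t]]
    pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / top)
    p <- file.path(dir, sprintf("tile_%03d.tif", grid$layout$tile_id[t]))
    tiff::writeTIFF(pages, p, bits.per.sample = 16L, compression = "none")
    paths <- c(paths, p)
  }
  sidecar <- list(layout = grid$layout, channel_names = grid$channel_names,
                  bit_depth = grid$bit_depth,
                  files = basename(paths))
  jp <- file.path(dir, "layout.json")
  jsonlite::write_json(sidecar, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}

#' Read a tile grid written by [write_tile_grid()]
#'
#' @param dir directory containing the TIFF tiles and `layout.json`.
#' @return a [tile_grid()].
#' @export
read_tile_grid <- function(dir) {
  jp <- file.path(dir, "layout.json")
  if (!file.exists(jp))
    stop_layout(sprintf("missing layout sidecar: %s", jp))
  sidecar <- jsonlite::read_json(jp, simplifyVector = TRUE)
  lay <- as.data.frame(sidecar$layout)
  channels <- sidecar$channel_names
  tiles <- lapply(seq_len(nrow(lay)), function(t) {
    p <- file.path(dir, sidecar$files[t])
    if (!file.exists(p)) stop_layout(sprintf("missing tile file: %s", p))
    pages <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    arr <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                            length(pages)),
                 dimnames = list(NULL, NULL, channels))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
    arr
  })
  tile_grid(tiles, lay, channels, sidecar$bit_depth)
}

#' Write an event table to CSV
#'
#' @param events event table data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_events_csv <- function(events, path) {
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read an event table from CSV
#'
#' @param path CSV file written by [write_events_csv()].
#' @return data.frame.
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("no such file: %s", path))
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write an event table to ARFF
#'
#' Mirrors the tabulated `.arff` event-table handoff: numeric attributes
#' for every measured column plus nominal attributes for identifiers and
#' class labels.
#'
#' @param events event table data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_events_arff <- function(events, path) {
  ev <- events
  for (nm in names(ev))
    if (is.character(ev[[nm]])) ev[[nm]] <- factor(ev[[nm]])
  foreign::write.arff(ev, path)
  invisible(path)
}

#' Read an event table from ARFF
#'
#' @param path ARFF file.
#' @return data.frame with factors converted back to character.
#' @export
read_events_arff <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("no such file: %s", path))
  ev <- foreign::read.arff(path)
  for (nm in names(ev))
    if (is.factor(ev[[nm]])) ev[[nm]] <- as.character(ev[[nm]])
  ev
}

#' Assemble a pipeline configuration
#'
#' One validated object holding every tunable of a run: the scenario preset,
#' image-pipeline parameters, gating options and seeds. Configurations
#' round-trip through YAML unchanged and carry a stable content hash that is
#' stamped on outputs as provenance.
#'
#' @param preset scenario preset name (see [make_scenario()]).
#' @param n_cells cells per sample (`NULL` for the preset default).
#' @param seed base seed.
#' @param image list of [pipeline_params()] overrides.
#' @param gating list with optional `channels`, `representative`, `manual`.
#' @param output_dir where drivers write results.
#' @return list of class `pipeline_config` with a `hash` attribute.
#' @export
pipeline_config <- function(preset = "fig2d_capture", n_cells = NULL,
                            seed = 100, image = list(), gating = list(),
                            output_dir = "results") {
  if (!preset %in% PRESET_NAMES)
    stop_lookup(sprintf("unknown preset '%s'", preset))
  img <- do.call(pipeline_params, image)
  if (img$min_area < 1 || img$hoechst_threshold <= 0)
    stop_config("image parameters out of range")
  cfg <- list(preset = preset, n_cells = n_cells, seed = as.integer(seed),
              image = unclass(img), gating = gating,
              output_dir = output_dir)
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Stable content hash of a configuration
#' @param cfg a `pipeline_config` (or plain list).
#' @return 8-hex-digit string.
#' @export
config_hash <- function(cfg) {
  fnv1a32(paste(deparse(unclass(cfg)[sort(names(unclass(cfg)))]),
                collapse = "\n"))
}

#' Save a configuration to YAML
#' @param cfg a [pipeline_config()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Load a configuration from YAML
#' @param path YAML file written by [save_config()].
#' @return a validated [pipeline_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("no such file: %s", path))
  raw <- yaml::read_yaml(path)
  pipeline_config(preset = raw$preset, n_cells = raw$n_cells,
                  seed = raw$seed, image = raw$image %||% list(),
                  gating = raw$gating %||% list(),
                  output_dir = raw$output_dir %||% "results")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
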