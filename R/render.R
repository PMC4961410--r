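#' Rendering parameters for the synthetic microscope
#'
#' Defaults emulate a stitched 10x acquisition: a uniform additive background
#' of 500 units per channel, Gaussian read noise with SD 50, 16-bit dynamic
#' range, a 2x2 tile grid with 10% overlap, and 5% of cells placed touching a
#' neighbour so the splitting stage is exercised.
#'
#' @param field_size field side in pixels, or `NULL` to size the field so
#'   cells cover roughly 18% of it.
#' @param tile_grid integer vector `c(rows, cols)` of the tile layout.
#' @param overlap_frac tile overlap as a fraction of tile size (>= 0).
#' @param background additive background level per channel (single value or
#'   one per channel).
#' @param noise_sd Gaussian noise SD in intensity units.
#' @param touch_rate fraction of cells deliberately placed touching a
#'   previously placed cell.
#' @param cytoplasm_extent pixels by which the stained "cytoplasm" disc
#'   extends beyond the nuclear radius for non-nuclear markers.
#' @param bit_depth bits per sample (16).
#' @param max_retries placement attempts per cell before a capacity error.
#' @return a list of class `image_params`.
#' @export
image_params <- function(field_size = NULL, tile_grid = c(2L, 2L),
                         overlap_frac = 0.10, background = 500,
                         noise_sd = 50, touch_rate = 0.05,
                         cytoplasm_extent = 3L, bit_depth = 16L,
                         max_retries = 500L) {
  if (overlap_frac < 0) stop_validation("overlap_frac must be >= 0")
  if (any(tile_grid < 1)) stop_validation("tile_grid entries must be >= 1")
  if (noise_sd < 0 || any(background < 0))
    stop_validation("noise_sd and background must be >= 0")
  structure(list(field_size = field_size, tile_grid = as.integer(tile_grid),
                 overlap_frac = overlap_frac, background = background,
                 noise_sd = noise_sd, touch_rate = touch_rate,
                 cytoplasm_extent = as.integer(cytoplasm_extent),
                 bit_depth = as.integer(bit_depth),
                 max_retries = as.integer(max_retries)),
            class = "image_params")
}

# integer pixel offsets of a disc of radius r around (0, 0)
disc_offsets <- function(r) {
  ri <- ceiling(r)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

place_cells <- function(radius, side, params) {
  n <- length(radius)
  margin <- ceiling(max(radius)) + params$cytoplasm_extent + 2
  if (side - 2 * margin < 4)
    stop_capacity("field too small for the requested cells")
  pos <- matrix(NA_real_, n, 2)
  touching <- runif(n) < params$touch_rate
  touching[1] <- FALSE
  for (i in seq_len(n)) {
    placed <- FALSE
    prev <- seq_len(i - 1L)
    for (try in seq_len(params$max_retries)) {
      if (touching[i]) {
        j <- sample(prev, 1L)
        ang <- runif(1, 0, 2 * pi)
        d <- 0.85 * (radius[i] + radius[j])
        cand <- pos[j, ] + d * c(cos(ang), sin(ang))
        others <- prev[prev != j]
      } else {
        cand <- runif(2, margin, side - margin)
        others <- prev
      }
      if (any(cand < margin) || any(cand > side - margin)) next
      if (length(others)) {
        dd <- sqrt((pos[others, 1] - cand[1])^2 +
                   (pos[others, 2] - cand[2])^2)
        if (any(dd < radius[others] + radius[i] + 2)) next
      }
      pos[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed)
      stop_capacity(sprintf(
        "could not place cell %d after %d attempts (field too crowded)",
        i, params$max_retries))
  }
  pos
}

#' Render an event table into multi-channel image tiles
#'
#' Places each cell at a rejection-sampled position (a configured fraction of
#' cells touching a neighbour), paints the nucleus as a filled disc in the
#' Hoechst channel and every other marker over a larger "cytoplasm" disc with
#' amplitude equal to the event's drawn intensity, adds per-channel background
#' and Gaussian noise, clips to the 16-bit range, and cuts the field into an
#' overlapping tile grid. The per-pixel ground-truth label mask is taken
#' before noise; pixels contested by touching nuclei go to the nearer
#' centroid, so every cell keeps exactly one label.
#'
#' @param events the `events` data.frame from [sample_events()].
#' @param params an [image_params()] object.
#' @param seed integer seed for the placement and noise streams (intensities
#'   were already drawn by [sample_events()]).
#' @return list of class `rendered_sample`:
#'   \describe{
#'     \item{grid}{a `tile_grid` (tiles, layout, channel names, bit depth).}
#'     \item{truth}{list with `mask` (label matrix, 0 = background, row k of
#'       `events` = label k), `field` (the noisy un-tiled field, the stitching
#'       oracle), and `events` (input table plus placed `row`/`col`).}
#'   }
#' @export
render_sample <- function(events, params = image_params(), seed = 1L) {
  n <- nrow(events)
  radius <- events$radius
  side <- params$field_size
  if (is.null(side)) {
    foot <- pi * (radius + params$cytoplasm_extent)^2
    side <- max(128L, ceiling(sqrt(sum(foot) / 0.18)))
  }
  side <- as.integer(side)

  set.seed(derive_seed(seed, "placement"))
  pos <- place_cells(radius, side, params)
  rows <- pos[, 1]; cols <- pos[, 2]

  channels <- CTC_CHANNELS
  bg <- rep(params$background, length.out = length(channels))
  names(bg) <- channels
  mask <- matrix(0L, side, side)
  bestd <- matrix(Inf, side, side)
  cyto_owner <- matrix(0L, side, side)
  cyto_bestd <- matrix(Inf, side, side)

  # each pixel carries the amplitude of exactly one cell (the nearest whose
  # disc covers it): cells are rendered as opaque discs, with no additive
  # stacking where neighbours overlap (stain mixing is out of scope)
  for (i in seq_len(n)) {
    nuc <- disc_offsets(radius[i])
    rr <- round(rows[i]) + nuc$dr; cc <- round(cols[i]) + nuc$dc
    idx <- cbind(rr, cc)
    d2 <- (rr - rows[i])^2 + (cc - cols[i])^2
    take <- d2 < bestd[idx]
    if (any(take)) {
      mask[idx[take, , drop = FALSE]] <- i
      bestd[idx[take, , drop = FALSE]] <- d2[take]
    }
    cyt <- disc_offsets(radius[i] + params$cytoplasm_extent)
    ccr <- round(rows[i]) + cyt$dr; ccc <- round(cols[i]) + cyt$dc
    cidx <- cbind(ccr, ccc)
    cd2 <- (ccr - rows[i])^2 + (ccc - cols[i])^2
    ctake <- cd2 < cyto_bestd[cidx]
    if (any(ctake)) {
      cyto_owner[cidx[ctake, , drop = FALSE]] <- i
      cyto_bestd[cidx[ctake, , drop = FALSE]] <- cd2[ctake]
    }
  }

  field <- lapply(channels, function(ch) matrix(0, side, side))
  names(field) <- channels
  nuc_px <- which(mask > 0L)
  field$Hoechst[nuc_px] <- events$Hoechst[mask[nuc_px]]
  cyt_px <- which(cyto_owner > 0L)
  for (ch in setdiff(channels, "Hoechst"))
    field[[ch]][cyt_px] <- events[[ch]][cyto_owner[cyt_px]]

  top <- 2^params$bit_depth - 1
  set.seed(derive_seed(seed, "noise"))
  for (ch in channels) {
    x <- field[[ch]] + bg[[ch]]
    if (params$noise_sd > 0)
      x <- x + rnorm(length(x), 0, params$noise_sd)
    field[[ch]] <- matrix(pmin(pmax(round(x), 0), top), side, side)
  }

  grid <- cut_tiles(field, params, channels, side)
  ev <- events
  ev$row <- rows; ev$col <- cols
  structure(list(grid = grid,
                 truth = list(mask = mask, field = field, events = ev)),
            class = "rendered_sample")
}

# Cut a field (list of channel matrices) into an overlapping tile grid.
cut_tiles <- function(field, params, channels, side) {
  gr <- params$tile_grid[1]; gc <- params$tile_grid[2]
  tile_h <- ceiling(side / (gr - (gr - 1) * params$overlap_frac))
  tile_w <- ceiling(side / (gc - (gc - 1) * params$overlap_frac))
  step_h <- if (gr > 1) floor((side - tile_h) / (gr - 1)) else 0L
  step_w <- if (gc > 1) floor((side - tile_w) / (gc - 1)) else 0L
  layout <- expand.grid(grid_row = seq_len(gr), grid_col = seq_len(gc))
  layout$tile_id <- seq_len(nrow(layout))
  layout$off_r <- (layout$grid_row - 1L) * step_h
  layout$off_c <- (layout$grid_col - 1L) * step_w
  layout$nrow <- pmin(tile_h, side - layout$off_r)
  layout$ncol <- pmin(tile_w, side - layout$off_c)
  tiles <- lapply(seq_len(nrow(layout)), function(t) {
    r0 <- layout$off_r[t]; c0 <- layout$off_c[t]
    arr <- array(0, dim = c(layout$nrow[t], layout$ncol[t], length(channels)),
                 dimnames = list(NULL, NULL, channels))
    for (k in seq_along(channels))
      arr[, , k] <- field[[channels[k]]][(r0 + 1):(r0 + layout$nrow[t]),
                                         (c0 + 1):(c0 + layout$ncol[t])]
    arr
  })
  tile_grid(tiles, layout[c("tile_id", "grid_row", "grid_col",
                            "off_r", "off_c", "nrow", "ncol")],
            channels, params$bit_depth)
}

#' Construct a tile grid object
#'
#' @param tiles list of `h x w x channels` arrays, one per tile.
#' @param layout data.frame with `tile_id`, `grid_row`, `grid_col`, `off_r`,
#'   `off_c` (0-based pixel offsets of the tile's top-left corner), `nrow`,
#'   `ncol`.
#' @param channel_names ordered channel labels shared by all tiles.
#' @param bit_depth bits per sample.
#' @return an object of class `tile_grid`.
#' @export
tile_grid <- function(tiles, layout, channel_names, bit_depth = 16L) {
  need <- c("tile_id", "off_r", "off_c", "nrow", "ncol")
  if (!all(need %in% names(layout)))
    stop_layout(paste("layout must provide:", paste(need, collapse = ", ")))
  if (any(layout$off_r < 0) || any(layout$off_c < 0))
    stop_layout("tile offsets must be non-negative")
  if (anyDuplicated(channel_names))
    stop_validation("channel names must be unique")
  nch <- vapply(tiles, function(t) dim(t)[3], integer(1))
  if (any(nch != length(channel_names)))
    stop_validation("all tiles must share the channel set")
  structure(list(tiles = tiles, layout = layout,
                 channel_names = channel_names,
                 bit_depth = as.integer(bit_depth)),
            class = "tile_grid")
}
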