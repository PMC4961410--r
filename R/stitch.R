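#' Stitch an overlapping tile grid into one large image
#'
#' Tiles are placed at the pixel offsets given in the layout sidecar
#' (registration is configured, never estimated) and pixels covered by more
#' than one tile are averaged. The output spans the bounding box of all
#' placed tiles.
#'
#' @param grid a [tile_grid()].
#' @return list of class `stitched_image`: one matrix per channel (named by
#'   channel), plus attributes `layout` (the provenance layout) and
#'   `background` (filled by [subtract_background()]).
#' @export
stitch_tiles <- function(grid) {
  if (!inherits(grid, "tile_grid")) stop_validation("grid must be a tile_grid")
  lay <- grid$layout
  dims <- t(vapply(grid$tiles, dim, integer(3)))
  if (nrow(unique(dims[, 3, drop = FALSE])) != 1)
    stop_validation("tiles disagree on channel count")
  H <- max(lay$off_r + dims[, 1])
  W <- max(lay$off_c + dims[, 2])
  channels <- grid$channel_names
  acc <- lapply(channels, function(ch) matrix(0, H, W))
  cnt <- matrix(0L, H, W)
  for (t in seq_len(nrow(lay))) {
    rs <- (lay$off_r[t] + 1):(lay$off_r[t] + dims[t, 1])
    cs <- (lay$off_c[t] + 1):(lay$off_c[t] + dims[t, 2])
    for (k in seq_along(channels))
      acc[[k]][rs, cs] <- acc[[k]][rs, cs] + grid$tiles[[t]][, , k]
    cnt[rs, cs] <- cnt[rs, cs] + 1L
  }
  if (any(cnt == 0))
    stop_layout("tile layout leaves gaps in the stitched image")
  out <- lapply(acc, function(a) a / cnt)
  names(out) <- channels
  structure(out, class = "stitched_image", layout = lay, background = NULL)
}

#' Subtract the average background fluorescence from each channel
#'
#' The per-channel background is estimated and subtracted before any
#' measurement, clamping at zero. The default estimator is the per-channel
#' median, which coincides with the mean background level when cells cover a
#' minority of the field and is robust to the bright cell pixels; the
#' alternative `"outside_mask"` averages pixels outside a provided
#' foreground mask.
#'
#' @param image a `stitched_image` (or any named list of channel matrices).
#' @param method `"median"` (default) or `"outside_mask"`.
#' @param mask logical/integer matrix of foreground pixels, required for
#'   `"outside_mask"`.
#' @return the image with background subtracted; the per-channel estimates
#'   are stored in `attr(, "background")`.
#' @export
subtract_background <- function(image, method = c("median", "outside_mask"),
                                mask = NULL) {
  method <- match.arg(method)
  channels <- names(image)
  est <- vapply(channels, function(ch) {
    if (method == "median") median(image[[ch]])
    else {
      if (is.null(mask)) stop_config("outside_mask estimator needs a mask")
      bgpx <- image[[ch]][mask == 0]
      if (!length(bgpx)) stop_validation("mask leaves no background pixels")
      mean(bgpx)
    }
  }, numeric(1))
  out <- lapply(channels, function(ch) pmax(image[[ch]] - est[[ch]], 0))
  names(out) <- channels
  structure(out, class = "stitched_image",
            layout = attr(image, "layout"), background = est)
}
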