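#' Label connected components of a binary image
#'
#' Run-length based connected-component labelling with 8-connectivity
#' (diagonal neighbours connected) by default. Row runs of foreground pixels
#' are nodes in a graph; runs in adjacent image rows are linked when their
#' column spans overlap (4-connectivity) or overlap after widening by one
#' pixel (8-connectivity); graph components are the labels.
#'
#' @param bw logical or 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of the same shape; 0 is background, components are
#'   labelled 1..K in raster order of their first pixel.
#' @export
label_components <- function(bw, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop_validation("connectivity must be 4 or 8")
  H <- nrow(bw); W <- ncol(bw)
  m <- matrix(as.integer(bw != 0), H, W)
  # run-length encode each image row: runs[k, ] = (row, c0, c1)
  run_list <- vector("list", H)
  for (r in seq_len(H)) {
    v <- m[r, ]
    if (!any(v == 1L)) next
    d <- diff(c(0L, v, 0L))
    starts <- which(d == 1L)
    run_list[[r]] <- cbind(row = r, c0 = starts, c1 = which(d == -1L) - 1L)
  }
  runs <- do.call(rbind, run_list)
  if (is.null(runs) || !nrow(runs)) return(matrix(0L, H, W))
  nruns <- nrow(runs)
  ids <- seq_len(nruns)
  idx_by_row <- split(ids, runs[, "row"])
  slack <- if (connectivity == 8) 1L else 0L
  edge_list <- list()
  for (r in 2:H) {
    a <- idx_by_row[[as.character(r - 1L)]]
    b <- idx_by_row[[as.character(r)]]
    if (is.null(a) || is.null(b)) next
    pair <- expand.grid(i = a, j = b)
    ok <- runs[pair$i, "c0"] <= runs[pair$j, "c1"] + slack &
          runs[pair$j, "c0"] <= runs[pair$i, "c1"] + slack
    if (any(ok))
      edge_list[[length(edge_list) + 1L]] <- cbind(pair$i[ok], pair$j[ok])
  }
  g <- igraph::make_empty_graph(n = nruns, directed = FALSE)
  if (length(edge_list)) {
    ed <- do.call(rbind, edge_list)
    g <- igraph::add_edges(g, as.vector(t(ed)))
  }
  comp <- igraph::components(g)$membership
  lab <- matrix(0L, H, W)
  for (k in ids)
    lab[runs[k, "row"], runs[k, "c0"]:runs[k, "c1"]] <- comp[k]
  relabel_raster(lab)
}

# relabel 1..K in order of first occurrence in R's column-major storage
# (deterministic)
relabel_raster <- function(lab) {
  u <- unique(as.vector(lab))
  u <- u[u != 0L]
  if (!length(u)) return(lab)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  out <- lab
  nz <- lab != 0L
  out[nz] <- map[lab[nz]]
  out
}

# pixel linear indices per label, in one pass
label_pixels <- function(lab) {
  nz <- which(lab > 0L)
  if (!length(nz)) return(list())
  split(nz, lab[nz])
}

# Distance-transform local maxima of one component patch, greedily
# suppressed so surviving seeds are >= min_dist apart (descending distance
# value, ties by raster order).
find_split_seeds <- function(dm, min_dist) {
  H <- nrow(dm); W <- ncol(dm)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- dm
  ismax <- dm > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ismax <- ismax & dm >= pad[2:(H + 1) + dr, 2:(W + 1) + dc]
  }
  cand <- which(ismax, arr.ind = TRUE)
  if (!nrow(cand)) return(cand)
  ord <- order(-dm[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    d <- sqrt((prev[, 1] - cand[i, 1])^2 + (prev[, 2] - cand[i, 2])^2)
    if (all(d >= min_dist)) keep[i] <- TRUE
  }
  cand[keep, , drop = FALSE]
}

# Seeded watershed on a small patch: component pixels are flooded in
# descending distance-transform order; an unlabelled pixel takes the label
# of an already-labelled 8-neighbour (lowest label on ties). Repeated passes
# handle pixels whose basin arrives late.
seeded_flood <- function(dm, inside, seeds) {
  lab <- matrix(0L, nrow(dm), ncol(dm))
  lab[seeds] <- seq_len(nrow(seeds))
  px <- which(inside & lab == 0L, arr.ind = TRUE)
  ord <- order(-dm[px], px[, 1], px[, 2])
  px <- px[ord, , drop = FALSE]
  H <- nrow(dm); W <- ncol(dm)
  repeat {
    changed <- FALSE
    todo <- lab[px] == 0L
    if (!any(todo)) break
    for (k in which(todo)) {
      r <- px[k, 1]; c <- px[k, 2]
      nb <- lab[max(1, r - 1):min(H, r + 1), max(1, c - 1):min(W, c + 1)]
      nb <- nb[nb > 0L]
      if (length(nb)) {
        lab[r, c] <- min(nb)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

#' Segment nuclei from the Hoechst channel
#'
#' Binarizes the (background-subtracted) nuclear channel at a user-defined
#' threshold, labels connected components with 8-connectivity, discards
#' components smaller than `min_area`, and splits components containing two
#' or more distance-transform maxima at least `split_min_distance` apart by
#' a watershed seeded at those maxima — this is how touching cells are
#' separated into individual nuclei. Labels are renumbered 1..K.
#'
#' @param hoechst numeric matrix, the nuclear channel.
#' @param threshold intensity threshold (> 0); pixels `>= threshold` are
#'   foreground. A threshold above the image maximum yields an empty mask
#'   with a warning.
#' @param min_area minimum component area in pixels (default 10).
#' @param split_min_distance minimum separation in pixels between
#'   distance-transform maxima for a component to be split (default 5);
#'   `NULL` or `Inf` disables splitting.
#' @return integer label matrix (class `label_mask`), 0 background.
#' @export
segment_nuclei <- function(hoechst, threshold, min_area = 10,
                           split_min_distance = 5) {
  if (threshold <= 0) stop_validation("threshold must be > 0")
  bw <- hoechst >= threshold
  if (!any(bw)) {
    warning("threshold exceeds image maximum; empty mask")
    return(structure(matrix(0L, nrow(hoechst), ncol(hoechst)),
                     class = "label_mask"))
  }
  lab <- label_components(bw, connectivity = 8)
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes < min_area)
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab <- relabel_raster(lab)

  if (!is.null(split_min_distance) && is.finite(split_min_distance) &&
      max(lab) > 0) {
    dm_full <- EBImage::distmap(lab > 0L)
    dm_full <- matrix(as.numeric(dm_full), nrow(lab), ncol(lab))
    out <- matrix(0L, nrow(lab), ncol(lab))
    nxt <- 0L
    W <- nrow(lab)
    for (px_lin in label_pixels(lab)) {
      pr <- (px_lin - 1L) %% W + 1L
      pc <- (px_lin - 1L) %/% W + 1L
      r0 <- min(pr); c0 <- min(pc)
      sub_in <- matrix(FALSE, max(pr) - r0 + 1L, max(pc) - c0 + 1L)
      sub_idx <- cbind(pr - r0 + 1L, pc - c0 + 1L)
      sub_in[sub_idx] <- TRUE
      sub_dm <- matrix(0, nrow(sub_in), ncol(sub_in))
      sub_dm[sub_idx] <- dm_full[px_lin]
      seeds <- find_split_seeds(sub_dm, split_min_distance)
      if (nrow(seeds) >= 2) {
        fl <- seeded_flood(sub_dm, sub_in, seeds)
        claimed <- fl[sub_idx]
        base <- nxt
        kept <- 0L
        keep_map <- integer(nrow(seeds))
        for (s in seq_len(nrow(seeds))) {
          area_s <- sum(claimed == s)
          if (area_s >= min_area) {
            kept <- kept + 1L
            keep_map[s] <- base + kept
          }
        }
        if (kept >= 2L) {
          nxt <- base + kept
          # sub-minimum slivers and unflooded leftovers join the first kept
          # basin of their component
          fallback <- keep_map[keep_map > 0L][1]
          newlab <- ifelse(claimed > 0L & keep_map[pmax(claimed, 1L)] > 0L,
                           keep_map[pmax(claimed, 1L)], fallback)
          out[px_lin] <- newlab
        } else {
          nxt <- nxt + 1L
          out[px_lin] <- nxt
        }
      } else {
        nxt <- nxt + 1L
        out[px_lin] <- nxt
      }
    }
    lab <- relabel_raster(out)
  }
  structure(lab, class = "label_mask")
}
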