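#' Derive a positive/negative cutoff from the density valley of an
#' intensity distribution
#'
#' Automates threshold placement "by clustering": intensities are
#' log10-transformed, a Gaussian kernel density estimate is taken with
#' Silverman's rule-of-thumb bandwidth, and the cutoff is placed at the
#' density minimum between the two highest-density modes, mapped back to
#' the intensity scale. A unimodal distribution yields a `no_valley` status
#' rather than a cutoff.
#'
#' @param values positive intensities (non-positive values are dropped;
#'   at least 50 values must remain).
#' @param method only `"kde_valley"` is implemented.
#' @param n_grid density grid size (default 512).
#' @param min_mode_sep minimum separation between modes, in log10 decades
#'   (default 0.3). Local maxima closer than this to a higher accepted mode
#'   are treated as ripples of the same cluster, not separate populations.
#' @param min_valley_depth a valley must dip below this fraction of the
#'   lower mode's density (default 0.75), otherwise the distribution is
#'   declared effectively unimodal.
#' @param min_mass each side of the cutoff must hold at least this fraction
#'   of the observations (default 0.01); KDE ripples in a sparse tail do
#'   not constitute a population.
#' @return list of class `ctc_cutoff`: `cutoff` (intensity units, `NA` when
#'   no valley), `status` (`"ok"` or `"no_valley"`), `modes` (intensity
#'   positions of the two modes used), `n`, `bw` (log10 bandwidth).
#' @export
derive_threshold <- function(values, method = "kde_valley", n_grid = 512,
                             min_mode_sep = 0.3, min_valley_depth = 0.75,
                             min_mass = 0.01) {
  if (method != "kde_valley") stop_config("unknown threshold method")
  v <- values[is.finite(values) & values > 0]
  if (length(v) < 50)
    stop_validation("need at least 50 positive values to derive a threshold")
  lv <- log10(v)
  d <- density(lv, bw = "nrd0", n = n_grid)
  y <- d$y; x <- d$x
  no_valley <- function(modes) structure(
    list(cutoff = NA_real_, status = "no_valley", modes = modes,
         n = length(v), bw = d$bw), class = "ctc_cutoff")
  # interior local maxima of the density curve
  im <- which(y[2:(n_grid - 1)] > y[1:(n_grid - 2)] &
              y[2:(n_grid - 1)] >= y[3:n_grid]) + 1L
  if (length(im) < 2) return(no_valley(10^x[im]))
  # non-maximum suppression: accept peaks in descending height, dropping
  # any within min_mode_sep decades of an already-accepted peak
  ord <- im[order(-y[im])]
  accepted <- ord[1]
  for (p in ord[-1])
    if (all(abs(x[p] - x[accepted]) >= min_mode_sep))
      accepted <- c(accepted, p)
  if (length(accepted) < 2) return(no_valley(10^x[accepted]))
  top2 <- accepted[1:2]
  lo <- min(top2); hi <- max(top2)
  valley <- lo + which.min(y[lo:hi]) - 1L
  if (y[valley] > min_valley_depth * min(y[top2]))
    return(no_valley(sort(10^x[top2])))
  below <- mean(lv < x[valley])
  if (min(below, 1 - below) < min_mass)
    return(no_valley(sort(10^x[top2])))
  structure(list(cutoff = 10^x[valley], status = "ok",
                 modes = sort(10^x[c(lo, hi)]), n = length(v), bw = d$bw),
            class = "ctc_cutoff")
}

#' Derive a set of channel cutoffs from a representative sample
#'
#' Thresholds are derived once, on one representative sample, and then
#' applied uniformly across the batch; the representative sample's id and
#' the derivation method are recorded as provenance.
#'
#' PD-L1 expression is continuous and need not separate into two density
#' modes; when the valley search fails for `PDL1` the cutoff falls back to
#' the 99th percentile of PD-L1 among the CD45-positive (leukocyte
#' reference) events of the representative sample — the usual
#' negative-reference positivity rule in cytometry. The fallback requires a
#' derived CD45 cutoff and is recorded as status `wbc_quantile`.
#'
#' @param events event table of the representative sample.
#' @param channels channels to derive cutoffs for.
#' @param manual named numeric vector of manual cutoff overrides (optional).
#' @param pdl1_reference_q quantile for the PD-L1 fallback (default 0.99).
#' @return list of class `threshold_set`: `cutoffs` (named numeric),
#'   `provenance` (representative sample id, method, per-channel status).
#' @export
derive_thresholds <- function(events,
                              channels = c("CD45", "CD11b", "pCK", "PDL1"),
                              manual = NULL, pdl1_reference_q = 0.99) {
  cutoffs <- numeric(0)
  status <- character(0)
  for (ch in channels) {
    if (!is.null(manual) && ch %in% names(manual)) {
      cutoffs[ch] <- manual[[ch]]
      status[ch] <- "manual"
      next
    }
    if (!ch %in% names(events))
      stop_validation(sprintf("channel '%s' absent from events", ch))
    th <- derive_threshold(events[[ch]])
    cutoffs[ch] <- th$cutoff
    status[ch] <- th$status
  }
  if ("PDL1" %in% channels && !is.finite(cutoffs[["PDL1"]]) &&
      "CD45" %in% names(cutoffs) && is.finite(cutoffs[["CD45"]])) {
    ref <- events$PDL1[events$CD45 >= cutoffs[["CD45"]]]
    if (length(ref) >= 50) {
      cutoffs["PDL1"] <- quantile(ref, pdl1_reference_q, names = FALSE)
      status["PDL1"] <- "wbc_quantile"
    }
  }
  structure(list(cutoffs = cutoffs,
                 provenance = list(
                   representative_sample = events$sample_id[1],
                   method = "kde_valley", status = status)),
            class = "threshold_set")
}

#' Define a gate region on one or two event axes
#'
#' @param x_axis channel or feature column name.
#' @param mode `"include"` (events inside the region are retained) or
#'   `"exclude"` (events inside are removed).
#' @param threshold for a 1-D gate: `c(value, polarity)` is expressed as
#'   `threshold` plus `polarity` (`">="` keeps/selects values at or above,
#'   `"<"` below).
#' @param polarity `">="` or `"<"` for 1-D gates.
#' @param y_axis second axis for 2-D gates.
#' @param rect 2-D axis-aligned rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param polygon 2-D polygon as a two-column matrix of vertices (closed
#'   implicitly; must not self-intersect).
#' @param label class label recorded for events this gate removes.
#' @return an object of class `ctc_gate`.
#' @export
gate <- function(x_axis, mode = c("include", "exclude"), threshold = NULL,
                 polarity = ">=", y_axis = NULL, rect = NULL, polygon = NULL,
                 label = NULL) {
  mode <- match.arg(mode)
  kind <- if (!is.null(threshold)) "threshold"
          else if (!is.null(rect)) "rect"
          else if (!is.null(polygon)) "polygon"
          else stop_config("gate needs a threshold, rect or polygon")
  if (kind != "threshold" && is.null(y_axis))
    stop_config("2-D gates need a y_axis")
  if (kind == "threshold" && !polarity %in% c(">=", "<"))
    stop_config("polarity must be '>=' or '<'")
  if (kind == "rect" &&
      (rect[1] > rect[2] || rect[3] > rect[4]))
    stop_validation("rectangle bounds must be ordered")
  if (kind == "polygon") {
    polygon <- as.matrix(polygon)
    if (ncol(polygon) != 2 || nrow(polygon) < 3)
      stop_validation("polygon needs >= 3 two-column vertices")
  }
  structure(list(x_axis = x_axis, y_axis = y_axis, mode = mode, kind = kind,
                 threshold = threshold, polarity = polarity, rect = rect,
                 polygon = polygon, label = label),
            class = "ctc_gate")
}

# Ray-casting point-in-polygon with an explicit boundary rule: points on an
# edge or vertex count as inside (the deterministic tie-break used by every
# gate region).
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  m <- length(px)
  inside <- logical(m)
  on_edge <- logical(m)
  for (e in seq_len(n)) {
    x1 <- xs[e]; y1 <- ys[e]; x2 <- xe[e]; y2 <- ye[e]
    # boundary test: collinear and within the segment's bounding box
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    on_seg <- abs(cross) < 1e-12 * (1 + abs(x2 - x1) + abs(y2 - y1)) &
      px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
      py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | on_seg
    # ray cast to the right, half-open vertex rule
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    inside <- xor(inside, crosses & !is.na(crosses))
  }
  inside | on_edge
}

#' Evaluate a gate over an event table
#'
#' Returns the per-event retention decision: events inside the gate region
#' are retained by an include gate and removed by an exclude gate. Points on
#' the region boundary count as inside.
#'
#' @param events event table.
#' @param g a [gate()].
#' @return logical vector, `TRUE` for retained events.
#' @export
apply_gate <- function(events, g) {
  if (!g$x_axis %in% names(events))
    stop_validation(sprintf("axis '%s' absent from events", g$x_axis))
  x <- events[[g$x_axis]]
  inside <- switch(g$kind,
    threshold = if (g$polarity == ">=") x >= g$threshold else x < g$threshold,
    rect = {
      if (!g$y_axis %in% names(events))
        stop_validation(sprintf("axis '%s' absent from events", g$y_axis))
      y <- events[[g$y_axis]]
      x >= g$rect[1] & x <= g$rect[2] & y >= g$rect[3] & y <= g$rect[4]
    },
    polygon = {
      if (!g$y_axis %in% names(events))
        stop_validation(sprintf("axis '%s' absent from events", g$y_axis))
      point_in_polygon(x, events[[g$y_axis]], g$polygon)
    })
  if (g$mode == "include") inside else !inside
}

#' Build a sequential gating strategy
#'
#' @param gates list of [gate()] objects, applied in order.
#' @param retained_label class label for events that survive every gate.
#' @return object of class `gating_strategy`.
#' @export
gating_strategy <- function(gates, retained_label = "CTC") {
  if (!length(gates)) stop_config("a strategy needs at least one gate")
  if (!all(vapply(gates, inherits, logical(1), "ctc_gate")))
    stop_validation("gates must be ctc_gate objects")
  structure(list(gates = gates, retained_label = retained_label),
            class = "gating_strategy")
}

#' Run a sequential gating strategy over an event table
#'
#' Gates are applied in order; once a gate removes an event, the decision is
#' final and the removing gate is recorded in the audit trail.
#'
#' @param events event table.
#' @param strategy a [gating_strategy()].
#' @return `events` with columns `gate_label` (the removing gate's label or
#'   the strategy's retained label) and `excluded_by` (1-based index of the
#'   removing gate, `NA` for retained events); attribute `gate_counts`
#'   records events in/out per gate.
#' @export
run_strategy <- function(events, strategy) {
  if (!inherits(strategy, "gating_strategy"))
    stop_validation("strategy must be a gating_strategy")
  n <- nrow(events)
  alive <- rep(TRUE, n)
  excluded_by <- rep(NA_integer_, n)
  label <- rep(strategy$retained_label, n)
  counts <- data.frame(gate = seq_along(strategy$gates),
                       n_in = NA_integer_, n_out = NA_integer_)
  for (i in seq_along(strategy$gates)) {
    g <- strategy$gates[[i]]
    counts$n_in[i] <- sum(alive)
    keep <- apply_gate(events, g)
    newly_out <- alive & !keep
    excluded_by[newly_out] <- i
    label[newly_out] <- if (is.null(g$label)) sprintf("excluded_gate%d", i)
                        else g$label
    alive <- alive & keep
    counts$n_out[i] <- sum(alive)
  }
  events$gate_label <- label
  events$excluded_by <- excluded_by
  attr(events, "gate_counts") <- counts
  events
}
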