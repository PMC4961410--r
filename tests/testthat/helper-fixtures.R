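# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; nothing is read from disk.

chan_ <- function(median, gsd) c(median = median, gsd = gsd)

# a minimal single-population scenario with overridable channel parameters
one_pop_scenario <- function(n_cells = 100, seed = 1, gsd = 1,
                             medians = NULL, name = "CTC", radius = 4) {
  med <- list(Hoechst = 20000, CD45 = 40, CD11b = 30, pCK = 150,
              PDL1 = 60, isotype = 8, capture = 800)
  if (!is.null(medians)) med[names(medians)] <- medians
  ch <- lapply(med, function(m) chan_(m, gsd))
  sample_scenario("one_pop", "EpCAM",
                  list(population_spec(name, 1, ch, chan_(radius, 1))),
                  n_cells = n_cells, seed = seed)
}

# two populations with planted pCK medians, equal weights
two_pop_scenario <- function(n_cells, seed, pck_a = 130, pck_b = 10,
                             gsd = 1.8) {
  mk <- function(name, pck, cd45) {
    ch <- list(Hoechst = chan_(20000, 1.3), CD45 = chan_(cd45, 1.6),
               CD11b = chan_(if (name == "MYELOID") 3000 else 30, 1.6),
               pCK = chan_(pck, gsd), PDL1 = chan_(30, 1.8),
               isotype = chan_(8, 1.8), capture = chan_(50, 1.8))
    population_spec(name, 0.5, ch, chan_(5, 1.15))
  }
  sample_scenario("two_pop", "EpCAM",
                  list(mk("MYELOID", pck_a, 250), mk("OTHER", pck_b, 40)),
                  n_cells = n_cells, seed = seed)
}

# brute-force connected-component oracle: BFS over explicit neighbour
# offsets, independent of the run-length implementation under test
bfs_label_oracle <- function(bw, connectivity = 8) {
  H <- nrow(bw); W <- ncol(bw)
  lab <- matrix(0L, H, W)
  offs <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  k <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!bw[i, j] || lab[i, j] > 0L) next
    k <- k + 1L
    queue <- matrix(c(i, j), 1)
    lab[i, j] <- k
    while (nrow(queue)) {
      cur <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      for (o in seq_len(nrow(offs))) {
        r <- cur[1] + offs[o, 1]; c <- cur[2] + offs[o, 2]
        if (r >= 1 && r <= H && c >= 1 && c <= W && bw[r, c] &&
            lab[r, c] == 0L) {
          lab[r, c] <- k
          queue <- rbind(queue, c(r, c))
        }
      }
    }
  }
  lab
}

# same-partition check, invariant to label numbering
same_partition <- function(a, b) {
  if (max(a) != max(b)) return(FALSE)
  nz <- a > 0L
  if (!identical(nz, b > 0L)) return(FALSE)
  !any(duplicated(unique(cbind(a[nz], b[nz]))[, 1])) &&
    !any(duplicated(unique(cbind(a[nz], b[nz]))[, 2]))
}

# paint discs into a logical matrix (independent of the renderer)
paint_discs <- function(side, centers, radii) {
  bw <- matrix(FALSE, side, side)
  for (i in seq_len(nrow(centers))) {
    g <- expand.grid(r = seq_len(side), c = seq_len(side))
    sel <- (g$r - centers[i, 1])^2 + (g$c - centers[i, 2])^2 <= radii[i]^2
    bw[cbind(g$r[sel], g$c[sel])] <- TRUE
  }
  bw
}

# exact binomial 99% CI bounds
binom_ci99 <- function(k, n) {
  as.numeric(stats::binom.test(k, n, conf.level = 0.99)$conf.int)
}
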