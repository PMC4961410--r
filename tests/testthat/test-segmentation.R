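# Nuclear segmentation: component labelling, touching-cell splitting,
# oracle equivalence and monotonicity.

test_that("two separated discs yield two labels", {
  bw <- paint_discs(40, rbind(c(12, 12), c(30, 30)), c(5, 5))
  img <- matrix(0, 40, 40); img[bw] <- 100
  mask <- segment_nuclei(img, threshold = 50, split_min_distance = NULL)
  expect_equal(max(mask), 2)
})

test_that("a dumbbell of two overlapping discs is split into two nuclei", {
  # centers 13 px apart, radius 8: overlap < radius
  bw <- paint_discs(48, rbind(c(24, 16), c(24, 29)), c(8, 8))
  img <- matrix(0, 48, 48); img[bw] <- 100
  merged <- segment_nuclei(img, threshold = 50, split_min_distance = NULL)
  expect_equal(max(merged), 1)
  split <- segment_nuclei(img, threshold = 50, split_min_distance = 5)
  expect_equal(max(split), 2)
  # both halves are substantial (each disc is ~200 px before the cut)
  expect_gt(min(tabulate(split[split > 0])), 80)
})

test_that("labelling matches a brute-force BFS oracle on random images", {
  set.seed(31)
  for (rep in 1:12) {
    bw <- matrix(runif(20 * 20) < 0.35, 20, 20)
    ours <- label_components(bw, connectivity = 8)
    oracle <- bfs_label_oracle(bw, connectivity = 8)
    expect_true(same_partition(ours, oracle))
    ours4 <- label_components(bw, connectivity = 4)
    oracle4 <- bfs_label_oracle(bw, connectivity = 4)
    expect_true(same_partition(ours4, oracle4))
  }
})

test_that("raising the threshold never increases the component count", {
  sc <- make_scenario("fig2d_capture", n_cells = 120)[[1]]
  drawn <- sample_events(sc)
  rend <- render_sample(drawn$events, seed = 6)
  hoechst <- subtract_background(stitch_tiles(rend$grid))$Hoechst
  ks <- vapply(c(1000, 2000, 5000, 10000, 18000), function(th)
    max(segment_nuclei(hoechst, th, split_min_distance = NULL)),
    numeric(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("a threshold above the image maximum warns and returns empty", {
  img <- matrix(10, 8, 8)
  expect_warning(mask <- segment_nuclei(img, threshold = 1e6), "empty mask")
  expect_equal(max(mask), 0)
})

test_that("segmentation recovers non-touching rendered nuclei at >= 95%
           precision and recall", {
  sc <- make_scenario("fig2d_capture", n_cells = 300)[[1]]
  drawn <- sample_events(sc)
  rend <- render_sample(drawn$events,
                        image_params(touch_rate = 0), seed = 12)
  sub <- subtract_background(stitch_tiles(rend$grid))
  mask <- segment_nuclei(sub$Hoechst, threshold = 2000)
  truth <- rend$truth$mask
  K <- max(mask)
  # match each segmented label to the truth label it mostly overlaps
  hits <- 0
  for (k in seq_len(K)) {
    tl <- truth[mask == k]
    tl <- tl[tl > 0]
    if (length(tl) && max(tabulate(tl)) / length(tl) > 0.5) hits <- hits + 1
  }
  expect_gte(hits / K, 0.95)                   # precision
  expect_gte(hits / nrow(drawn$events), 0.95)  # recall
})
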