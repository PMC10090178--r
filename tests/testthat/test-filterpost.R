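test_that("moment-ellipse axes recover closed-form shapes", {
  # filled disc radius 20: coordinate variance r^2/4, so both axes = 2r
  disc <- disc_coords(50, 50, 20)
  fit <- fit_ellipse(disc)
  expect_lt(abs(fit$minor_px - 40), 1)
  expect_lt(abs(fit$major_px - 40), 1)
  # 10 x 30 axis-aligned rectangle: uniform variance w^2/12 across the
  # short side, so minor = 10 * 4 / sqrt(12) ~ 11.55
  rect <- as.matrix(expand.grid(row = 1:10, col = 1:30))
  fit <- fit_ellipse(rect)
  expect_lt(abs(fit$minor_px - 11.55), 0.2)
  expect_gt(fit$major_px, fit$minor_px)
  # degenerate sets
  expect_identical(fit_ellipse(cbind(5, 5))$minor_px, 1)
  collinear <- cbind(1:9, rep(4, 9))
  expect_identical(fit_ellipse(collinear)$minor_px, 1)
  expect_error(fit_ellipse(cbind(numeric(0), numeric(0))), "Empty")
})

test_that("segment_records matches fit_ellipse on each instance", {
  img <- matrix(40L, 120, 120)
  img <- draw_disc(img, 40, 40, 15, 200L)
  img <- draw_disc(img, 90, 90, 8, 180L)
  labels <- matrix(0L, 120, 120)
  labels[draw_disc(matrix(0L, 120, 120), 40, 40, 15, 1L) == 1L] <- 1L
  labels[draw_disc(matrix(0L, 120, 120), 90, 90, 8, 1L) == 1L] <- 2L
  part <- as_test_partition(img)
  rec <- segment_records(labels, part)
  expect_identical(rec$id, 1:2)
  for (i in 1:2) {
    coords <- which(labels == i, arr.ind = TRUE)
    fit <- fit_ellipse(coords)
    expect_equal(rec$minor_px[i], fit$minor_px, tolerance = 1e-8)
    expect_equal(rec$major_px[i], fit$major_px, tolerance = 1e-8)
  }
  expect_equal(rec$diameter_um, rec$minor_px * 0.75)
})

test_that("intensity filter removes segments fainter than the partition mean", {
  img <- matrix(100L, 30, 30)
  img[1:3, 1:3] <- 80L    # faint segment
  img[1:3, 6:8] <- 120L   # bright segment
  labels <- matrix(0L, 30, 30)
  labels[1:3, 1:3] <- 1L; labels[1:3, 6:8] <- 2L
  part <- as_test_partition(img)
  rec <- intensity_filter(segment_records(labels, part), part)
  thr <- mean(img)
  expect_lt(rec$mean_gray[1], thr)
  expect_identical(rec$status, c("removed", "kept"))
  expect_identical(rec$removal_reason, c("intensity", "none"))
  # a segment exactly at the threshold is kept (strict inequality)
  img2 <- matrix(100L, 10, 10)
  labels2 <- matrix(0L, 10, 10); labels2[3:4, 3:4] <- 1L
  part2 <- as_test_partition(img2)
  rec2 <- intensity_filter(segment_records(labels2, part2), part2)
  expect_identical(rec2$status, "kept")
})

test_that("faint extracellular blobs are exactly what intensity removes", {
  img <- matrix(55L, 250, 250)
  labels <- matrix(0L, 250, 250)
  centers <- expand.grid(r = seq(35, 215, by = 45), c = seq(45, 205, by = 80))
  lab <- 0L
  classes <- character(0)
  for (i in seq_len(15)) {
    lab <- lab + 1L
    bright <- i <= 10   # 10 neurons, then 5 faint blobs
    val <- if (bright) 170L else 63L
    r <- if (bright) 15 else 6
    m <- draw_disc(matrix(0L, 250, 250), centers$r[i], centers$c[i], r, 1L)
    img[m == 1L] <- val
    labels[m == 1L] <- lab
    classes <- c(classes, if (bright) "neuron" else "blob")
  }
  part <- as_test_partition(img)
  rec <- intensity_filter(segment_records(labels, part), part)
  expect_identical(rec$status == "removed", classes == "blob")
})

test_that("the diameter filter applies mean - k.SD with strict inequality", {
  rec <- tibble::tibble(
    id = 1:5, pixel_count = 100L, mean_gray = 150,
    row = 1, col = 1, major_px = 30, minor_px = c(10, 12, 14, 16, 18) / 0.75,
    angle = 0, diameter_um = c(10, 12, 14, 16, 18),
    touches_edge = FALSE, status = "kept", removal_reason = "none")
  out <- diameter_filter(rec, filter_params(k_sd = 0.75))
  expect_equal(attr(out, "diameter_threshold"), 14 - 0.75 * sqrt(10),
               tolerance = 1e-12)
  expect_equal(attr(out, "diameter_threshold"), 11.628, tolerance = 1e-3)
  expect_identical(out$status, c("removed", rep("kept", 4)))
  # equal diameters: sd 0, threshold = mean, strict < keeps all
  rec2 <- dplyr::mutate(rec, diameter_um = 14)
  out2 <- diameter_filter(rec2, filter_params(k_sd = 0.75))
  expect_true(all(out2$status == "kept"))
  # huge k: negative threshold removes nothing
  out3 <- diameter_filter(rec, filter_params(k_sd = 50))
  expect_true(all(out3$status == "kept"))
  # fewer than 2 survivors: warning, no-op
  expect_warning(diameter_filter(rec[1, ], filter_params()), "skipped")
})

test_that("raising k_sd never removes fewer records", {
  set.seed(42)
  rec <- tibble::tibble(
    id = 1:50, pixel_count = 100L, mean_gray = 150, row = 1, col = 1,
    major_px = 30, minor_px = 20, angle = 0,
    diameter_um = rlnorm(50, log(15), 0.4),
    touches_edge = FALSE, status = "kept", removal_reason = "none")
  removed <- vapply(c(0, 0.25, 0.5, 0.75, 1, 1.5), function(k)
    sum(diameter_filter(rec, filter_params(k_sd = k))$status == "removed"),
    numeric(1))
  expect_true(all(diff(removed) <= 0))  # larger k, smaller threshold
})

test_that("edge exclusion removes exactly border-touching instances", {
  labels <- matrix(0L, 20, 20)
  labels[1:4, 8:10] <- 1L          # touches top border
  labels[9:11, 9:11] <- 2L         # interior
  labels[18:19, 2:4] <- 3L         # 1 px from border: kept
  img <- matrix(100L, 20, 20); img[labels > 0] <- 180L
  part <- as_test_partition(img)
  rec <- edge_exclusion(segment_records(labels, part))
  expect_identical(rec$status, c("removed", "kept", "kept"))
  expect_identical(rec$removal_reason[1], "edge")
  # an instance tiling the whole frame touches all borders
  full <- matrix(1L, 20, 20)
  rec2 <- edge_exclusion(segment_records(full, part))
  expect_identical(rec2$status, "removed")
})

test_that("run_filters orders stages, tallies and freezes reproducibly", {
  expect_identical(run_filters(matrix(0L, 10, 10),
                               as_test_partition(matrix(50L, 10, 10)))$tally$n_kept,
                   0L)
  fx <- default_test_partition(41)
  fl <- run_filters(fx$rendered$gt_labels, fx$partition)
  tl <- fl$tally
  expect_identical(tl$n_unfiltered, max(fx$rendered$gt_labels))
  expect_identical(tl$n_unfiltered - tl$n_kept,
                   tl$n_removed_intensity + tl$n_removed_diameter +
                     tl$n_removed_edge)
  expect_true(tl$pct_kept >= 0 && tl$pct_kept <= 100)
  # frozen-threshold idempotence: re-filtering the kept set with the
  # first-pass statistics removes nothing further
  kept_map <- filtered_label_map(fx$rendered$gt_labels, fl$records)
  rec2 <- segment_records(kept_map, fx$partition)
  rec2 <- diameter_filter(rec2, filter_params(),
                          stats = list(mean = fl$thresholds$diameter_mean,
                                       sd = fl$thresholds$diameter_sd))
  expect_true(all(rec2$status == "kept"))
})

test_that("filters recover planted classes on default partitions", {
  sens <- num <- den <- rej_n <- rej_d <- 0
  for (s in c(61, 62)) {
    fx <- default_test_partition(s)
    fl <- run_filters(fx$rendered$gt_labels, fx$partition)
    gt <- records_with_classes(fl$records, fx$rendered)
    nonneuron <- gt$render_class %in% c("glia", "profile", "blob")
    num <- num + sum(gt$in_plane & gt$status == "kept")
    den <- den + sum(gt$in_plane)
    rej_n <- rej_n + sum(nonneuron & gt$status == "removed")
    rej_d <- rej_d + sum(nonneuron)
  }
  expect_gte(num / den, 0.90)       # planted-neuron sensitivity
  expect_gte(rej_n / rej_d, 0.80)   # planted non-neuron rejection
})
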