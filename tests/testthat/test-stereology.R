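test_that("frame placement derives spacing, asf and errors correctly", {
  roi <- cbind(c(0, 500, 500, 0), c(0, 0, 500, 500))
  # exhaustive tiling: spacing = frame size gives asf = 1
  pl <- place_frames(roi, fractionator_params(grid_spacing_um = 50),
                     offset = c(10, 10))
  expect_equal(pl$asf, 1)
  # target 10 frames on a 500 um square: spacing ~ 158.1 um
  pl2 <- place_frames(roi, fractionator_params(target_frames = 10),
                      offset = c(0, 0))
  expect_equal(pl2$spacing, sqrt(500^2 / 10), tolerance = 1e-12)
  expect_equal(pl2$spacing, 158.1, tolerance = 1e-3)
  # mean frame count over offsets matches the area ratio
  set.seed(31)
  counts <- replicate(200, nrow(place_frames(
    roi, fractionator_params(target_frames = 10))$frames))
  expect_lt(abs(mean(counts) - 10), 1)
  expect_error(place_frames(cbind(c(0, 1, 0), c(0, 0, 0)),
                            fractionator_params()), "positive")
  expect_error(place_frames(roi, fractionator_params(grid_spacing_um = 30)),
               "smaller")
})

test_that("the disector counts respect guards and the half-open frame", {
  cells <- tibble::tibble(
    x_um = c(25, 25, 25), y_um = c(25, 25, 25),
    z_um = c(1, 8, 19), diameter_um = 18)
  cells$nucl_z_um <- cells$z_um
  slab <- manual_slab(cells, 50, 50)
  fr <- count_frame(c(0, 0), slab, fractionator_params())
  # z = 1 is inside the top guard; z = 19 beyond guard + disector: only z = 8
  expect_identical(fr$Q, 1L)
  expect_equal(fr$t_um, 20.39)
  # frame boundary rule: x = x0 excluded, x = x0 + w included
  cells2 <- tibble::tibble(x_um = c(0, 50), y_um = c(25, 25), z_um = 8,
                           diameter_um = 18)
  cells2$nucl_x_um <- cells2$x_um; cells2$nucl_z_um <- cells2$z_um
  slab2 <- manual_slab(cells2, 50, 50)
  expect_identical(count_frame(c(0, 0), slab2, fractionator_params())$Q, 1L)
})

test_that("an exhaustive tiling counts every nucleolus exactly once", {
  spec <- slab_spec(width_um = 400, height_um = 400,
                    densities = c(pyramidal = 500, glial = 0, blob = 0),
                    seed = 7)
  slab <- generate_slab(spec)
  params <- fractionator_params(grid_spacing_um = 50, guard_um = 0,
                                disector_h_um = slab$thickness_um)
  roi <- cbind(c(-100, 500, 500, -100), c(-100, -100, 500, 500))
  for (off in list(c(0, 0), c(13, 31), c(49.9, 0.1))) {
    pl <- place_frames(roi, params, offset = off)
    q <- vapply(seq_len(nrow(pl$frames)), function(k)
      count_frame(pl$frames[k, ], slab, params)$Q, integer(1))
    expect_identical(sum(q), nrow(slab$cells))
  }
})

test_that("the fractionator equation reproduces identities and hand values", {
  params <- fractionator_params(disector_h_um = 10, ssf = 1)
  # sum Q = 0 gives N = 0
  est0 <- fractionator_estimate(tibble::tibble(Q = c(0L, 0L), t_um = 10),
                                params, asf = 0.5)
  expect_identical(est0$N, 0)
  # asf = ssf = 1 and t = h collapse N to sum Q
  est1 <- fractionator_estimate(tibble::tibble(Q = c(3L, 7L), t_um = 10),
                                params, asf = 1)
  expect_identical(est1$N, 10)
  # hand evaluation: 100 * (20.39/10) * (1/0.01) * 1 = 20390
  est2 <- fractionator_estimate(tibble::tibble(Q = 100L, t_um = 20.39),
                                params, asf = 0.01)
  expect_equal(est2$N, 20390, tolerance = 1e-12)
  expect_error(fractionator_estimate(tibble::tibble(Q = 1L, t_um = 10)[0, ],
                                     params, 1), "at least one")
  expect_error(fractionator_estimate(tibble::tibble(Q = 1L, t_um = 10),
                                     params, 0), "positive")
})

test_that("N scales linearly in 1/asf and t/h", {
  params <- fractionator_params(disector_h_um = 10)
  fr <- tibble::tibble(Q = c(5L, 15L), t_um = 20)
  n1 <- fractionator_estimate(fr, params, asf = 0.2)$N
  n2 <- fractionator_estimate(fr, params, asf = 0.1)$N
  expect_equal(n2, 2 * n1)
  params2 <- fractionator_params(disector_h_um = 5)
  n3 <- fractionator_estimate(fr, params2, asf = 0.2)$N
  expect_equal(n3, 2 * n1)
})

test_that("replicate runs are reproducible and tidyable", {
  spec <- slab_spec(width_um = 400, height_um = 400,
                    densities = c(pyramidal = 400, glial = 0, blob = 0),
                    seed = 3)
  slab <- generate_slab(spec)
  r1 <- run_stereology(slab, params = fractionator_params(grid_spacing_um = 100),
                       n_replicates = 5, seed = 11)
  r2 <- run_stereology(slab, params = fractionator_params(grid_spacing_um = 100),
                       n_replicates = 5, seed = 11)
  expect_identical(r1$replicates$N, r2$replicates$N)
  expect_identical(nrow(tidy(r1)), 5L)
  expect_s3_class(glance(r1), "tbl_df")
  expect_error(run_stereology(slab, params = fractionator_params(
    disector_h_um = 30)), "exceed")
})

test_that("the estimator is unbiased over random grid offsets", {
  spec <- slab_spec(width_um = 900, height_um = 900,
                    densities = c(pyramidal = 700, glial = 0, blob = 0),
                    seed = 17)
  slab <- generate_slab(spec)
  roi <- cbind(c(100, 800, 800, 100), c(100, 100, 800, 800))
  run <- run_stereology(slab, roi,
                        fractionator_params(grid_spacing_um = 100),
                        n_replicates = 120, seed = 18)
  expect_lt(abs(run$mean_N - run$true_count) / run$true_count, 0.05)
})
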