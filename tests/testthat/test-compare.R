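test_that("Dice obeys its defining identities", {
  a <- matrix(0L, 10, 10); a[2:5, 2:5] <- 1L
  expect_identical(dice(a, a), 1)
  b <- matrix(0L, 10, 10); b[7:9, 7:9] <- 1L
  expect_identical(dice(a, b), 0)
  # |A| = |B| = 4, overlap 2 -> 0.5
  a2 <- matrix(0L, 4, 4); a2[1, 1:4] <- 1L
  b2 <- matrix(0L, 4, 4); b2[1, 3:4] <- 1L; b2[2, 1:2] <- 1L
  expect_identical(dice(a2, b2), 0.5)
  # symmetric, relabel-invariant, shape-checked
  expect_identical(dice(b2, a2), 0.5)
  relab <- a; relab[relab > 0] <- 99L
  expect_identical(dice(relab, a), 1)
  expect_warning(d0 <- dice(matrix(0L, 3, 3), matrix(0L, 3, 3)), "vacuously")
  expect_identical(d0, 1)
  expect_identical(dice(a, matrix(0L, 10, 10)), 0)
  expect_error(dice(a, matrix(0L, 5, 5)), "shape")
})

test_that("mask comparison enumerates the expected pairs", {
  set.seed(9)
  base <- matrix(0L, 30, 30); base[10:20, 10:20] <- 1L
  autos <- lapply(1:5, function(i) base)
  raters <- lapply(1:5, function(i) lapply(1:3, function(j) base))
  ma <- compare_masks(autos, raters)
  # 3 raters x 5 vignettes and C(3,2) x 5 pairs
  expect_identical(sum(ma$pairs$comparison == "auto_vs_rater"), 15L)
  expect_identical(sum(ma$pairs$comparison == "rater_vs_rater"), 15L)
  # identical masks: all Dice 1, degenerate zero-difference test
  expect_true(all(ma$pairs$dice == 1))
  expect_identical(ma$test$p.value, 1)
  expect_error(compare_masks(base, list(base)), "2 rater")
})

test_that("symmetric boundary jitter yields matched group means", {
  spec <- slab_spec(width_um = 400, height_um = 400, seed = 71)
  rp <- render_partition(generate_slab(spec), seed = 72)
  autos <- list(); raters <- list()
  for (v in 1:5) {
    autos[[v]] <- jitter_mask(rp$gt_labels, 100 + v)
    raters[[v]] <- lapply(1:3, function(r) jitter_mask(rp$gt_labels,
                                                       200 + 10 * v + r))
  }
  ma <- compare_masks(autos, raters)
  gm <- ma$group_means$mean_dice
  expect_lt(abs(gm[1] - gm[2]), 0.05)
  expect_s3_class(glance(ma), "tbl_df")
})

test_that("method_stats validates its input table", {
  tab <- tibble::tibble(partition_id = 1:6,
                        subregion = rep(c("CA1", "CA2", "CA3"), 2),
                        automated = c(1, 2, 3, 4, 5, 6),
                        manual = c(2, 4, 6, 8, 10, 12))
  expect_error(method_stats(tab[, 1:3]), "columns")
  expect_error(method_stats(dplyr::mutate(tab, manual = NA_real_)),
               "Unpaired")
  expect_error(method_stats(dplyr::mutate(tab, subregion = "CA1")),
               "3 subregions")
  expect_error(method_stats(tab[0, ]), "Empty")
})

test_that("Spearman is exactly 1 under a monotone method relation", {
  set.seed(14)
  tab <- tibble::tibble(
    partition_id = 1:30,
    subregion = rep(c("CA1", "CA2", "CA3", "CA4", "Sub"), 6),
    automated = rlnorm(30, log(1000), 0.8))
  tab$manual <- 2 * tab$automated
  ms <- method_stats(tab)
  expect_equal(unname(ms$spearman_partition$estimate), 1)
  expect_equal(unname(ms$spearman_subregion$estimate), 1)
  # invariance under any strictly monotone transform
  tab2 <- dplyr::mutate(tab, manual = exp(automated / max(automated)))
  ms2 <- method_stats(tab2)
  expect_equal(unname(ms2$spearman_partition$estimate), 1)
})

test_that("identical methods give the degenerate paired Wilcoxon", {
  tab <- tibble::tibble(partition_id = 1:12,
                        subregion = rep(c("CA1", "CA2", "CA3"), 4),
                        automated = rep(c(10, 20, 30), 4))
  tab$manual <- tab$automated
  ms <- method_stats(tab)
  expect_true(ms$wilcoxon$degenerate)
  expect_identical(ms$wilcoxon$p.value, 1)
})

test_that("Dunn's z statistics match the hand-computed small example", {
  # three groups of two with no ties: rank means 1.5, 3.5, 5.5 and
  # se = sqrt(N(N+1)/12 * (1/2 + 1/2)) = sqrt(3.5)
  d <- nisslcount:::dunn_test(c(1, 2, 3, 4, 5, 6),
                              rep(c("a", "b", "c"), each = 2))
  se <- sqrt(3.5)
  expect_equal(d$z, c(-2 / se, -4 / se, -2 / se), tolerance = 1e-12)
  # Holm adjustment is monotone in raw-p rank and never below raw p
  expect_true(all(d$p.adj >= d$p.value))
  ord <- order(d$p.value)
  expect_true(all(diff(d$p.adj[ord]) >= -1e-15))
})

test_that("the full stats battery reports every declared component", {
  set.seed(15)
  subr <- rep(c("CA1", "CA1u", "CA2", "CA2u", "CA3", "CA3u", "CA4", "Sub",
                "Subu"), length.out = 45)
  mu <- setNames(c(4000, 1600, 500, 1000, 1100, 1700, 1300, 4400, 4100),
                 unique(subr))
  manual <- rlnorm(45, log(2 * mu[subr]), 0.3)
  tab <- tibble::tibble(partition_id = 1:45, subregion = subr,
                        automated = rlnorm(45, log(mu[subr]), 0.3),
                        manual = manual)
  ms <- method_stats(tab)
  expect_identical(nrow(ms$kruskal), 2L)
  expect_identical(nrow(ms$dunn), 72L)  # 2 methods x C(9, 2) subregion pairs
  expect_identical(nrow(ms$descriptives), 18L)
  expect_true(all(c("p25", "median", "p75", "mean", "sd", "sem",
                    "ci95_lo", "ci95_hi") %in% names(ms$descriptives)))
  td <- tidy(ms)
  expect_true(all(c("wilcoxon_paired", "spearman_partition",
                    "spearman_subregion", "kruskal_automated",
                    "kruskal_manual") %in% td$test))
  expect_s3_class(glance(ms), "tbl_df")
})
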