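#' Dice coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)` on the binarized (label > 0) masks, so the score
#' is invariant to instance relabeling. Two empty masks agree vacuously
#' (Dice 1, with a warning); exactly one empty mask scores 0.
#'
#' @param a,b Matrices of equal shape (logical, or label images binarized
#'   by `> 0`).
#' @return Dice score in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) abort("Masks differ in shape.")
  A <- a > 0; B <- b > 0
  sa <- sum(A); sb <- sum(B)
  if (sa + sb == 0L) {
    warn("Both masks empty; Dice is vacuously 1.")
    return(1)
  }
  2 * sum(A & B) / (sa + sb)
}

#' Compare automated masks with manual rater masks across vignettes
#'
#' For each vignette, computes Dice scores for every automated-versus-rater
#' pair and every rater-versus-rater pair, then tests whether the two
#' groups of scores differ. The default test is the independent two-sample
#' (Welch) t-test; `paired = TRUE` pairs the groups instead (requires equal
#' group sizes). The report records which form was used.
#'
#' @param auto_masks A mask matrix, or a list of mask matrices (one per
#'   vignette).
#' @param rater_masks A list of rater masks (single vignette) or a list of
#'   such lists (one per vignette); at least 2 raters per vignette.
#' @param paired Use the paired t-test form.
#' @return Object of class `mask_agreement`: `pairs` tibble (vignette,
#'   comparison, a, b, dice), `test` (htest), `group_means` tibble with
#'   mean and SEM per comparison group.
#' @export
compare_masks <- function(auto_masks, rater_masks, paired = FALSE) {
  if (is.matrix(auto_masks)) {
    auto_masks <- list(auto_masks)
    rater_masks <- list(rater_masks)
  }
  stopifnot(length(auto_masks) == length(rater_masks))
  rows <- list()
  for (v in seq_along(auto_masks)) {
    raters <- rater_masks[[v]]
    if (length(raters) < 2L) abort("Need at least 2 rater masks per vignette.")
    for (r in seq_along(raters)) {
      rows[[length(rows) + 1L]] <- tibble(
        vignette = v, comparison = "auto_vs_rater",
        a = "auto", b = paste0("rater", r),
        dice = dice(auto_masks[[v]], raters[[r]]))
    }
    cmb <- utils::combn(length(raters), 2)
    for (k in seq_len(ncol(cmb))) {
      rows[[length(rows) + 1L]] <- tibble(
        vignette = v, comparison = "rater_vs_rater",
        a = paste0("rater", cmb[1, k]), b = paste0("rater", cmb[2, k]),
        dice = dice(raters[[cmb[1, k]]], raters[[cmb[2, k]]]))
    }
  }
  pairs <- bind_rows(rows)
  g1 <- pairs$dice[pairs$comparison == "auto_vs_rater"]
  g2 <- pairs$dice[pairs$comparison == "rater_vs_rater"]
  test <- if (stats::var(g1) + stats::var(g2) < 1e-20) {
    # identical scores in both groups: difference is exactly zero
    structure(list(statistic = c(t = 0), parameter = c(df = NA_real_),
                   p.value = 1, method = "degenerate (zero variance)",
                   estimate = c(mean_diff = mean(g1) - mean(g2))),
              class = "htest")
  } else if (paired) {
    t.test(g1, g2, paired = TRUE)
  } else {
    t.test(g1, g2)
  }
  gm <- pairs %>% group_by(.data$comparison) %>%
    summarise(n = n(), mean_dice = mean(.data$dice),
              sem = sd(.data$dice) / sqrt(n()), .groups = "drop")
  structure(list(pairs = pairs, test = test, group_means = gm,
                 paired = paired),
            class = "mask_agreement")
}

#' @export
print.mask_agreement <- function(x, ...) {
  cat("<mask_agreement>\n")
  print(x$group_means)
  cat(sprintf("%s t = %.3f, p = %.4f\n",
              if (x$paired) "paired" else "Welch two-sample",
              unname(x$test$statistic), x$test$p.value))
  invisible(x)
}

#' @method tidy mask_agreement
#' @export
tidy.mask_agreement <- function(x, ...) x$pairs

#' @method glance mask_agreement
#' @export
glance.mask_agreement <- function(x, ...) {
  gm <- x$group_means
  tibble(mean_dice_auto = gm$mean_dice[gm$comparison == "auto_vs_rater"],
         mean_dice_rater = gm$mean_dice[gm$comparison == "rater_vs_rater"],
         statistic = unname(x$test$statistic),
         p.value = x$test$p.value, paired = x$paired)
}

# Dunn's z post-hoc tests after Kruskal-Wallis, with tie correction.
# z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j)),
# T = sum(t^3 - t) / (12 (N - 1)) over tie groups.
dunn_test <- function(values, groups, p_adjust_method = "holm") {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  cmb <- utils::combn(length(lv), 2)
  z <- numeric(ncol(cmb)); lab1 <- lab2 <- character(ncol(cmb))
  for (k in seq_len(ncol(cmb))) {
    i <- cmb[1, k]; j <- cmb[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ni[i] + 1 / ni[j]))
    z[k] <- (rbar[i] - rbar[j]) / se
    lab1[k] <- lv[i]; lab2[k] <- lv[j]
  }
  p <- 2 * pnorm(-abs(z))
  tibble(group1 = lab1, group2 = lab2, z = as.numeric(z),
         p.value = p, p.adj = p.adjust(p, method = p_adjust_method))
}

describe_by <- function(x) {
  q <- quantile(x, c(.25, .5, .75), names = FALSE)
  n <- length(x)
  se <- sd(x) / sqrt(n)
  tcrit <- if (n > 1) qt(0.975, n - 1) else NA_real_
  tibble(n = n, p25 = q[1], median = q[2], p75 = q[3],
         mean = mean(x), sd = sd(x), sem = se,
         ci95_lo = mean(x) - tcrit * se, ci95_hi = mean(x) + tcrit * se)
}

#' Method-comparison statistics for automated estimates vs stereology counts
#'
#' Runs the full nonparametric comparison battery on a paired method table:
#' Shapiro-Wilk normality screens, a paired Wilcoxon signed-rank test of
#' automated versus manual counts across partitions, Spearman rank
#' correlations at both granularities (subregion means, and individual
#' partitions), two Kruskal-Wallis H tests of subregion effects (one per
#' method) with Dunn's post-hoc z tests under Holm correction, and
#' Table-style descriptive summaries (quartiles, mean, SD, SEM, 95% CI) per
#' subregion and method. All tests are two-sided at alpha = 0.05.
#'
#' @param table Data frame with columns `partition_id`, `subregion`,
#'   `automated`, `manual` (optionally `case`, `level`).
#' @return Object of class `method_stats` with components `shapiro`,
#'   `wilcoxon`, `spearman_subregion`, `spearman_partition`, `kruskal`,
#'   `dunn`, `descriptives`.
#' @export
method_stats <- function(table) {
  table <- as_tibble(table)
  need <- c("partition_id", "subregion", "automated", "manual")
  if (!all(need %in% names(table)))
    abort(paste("`table` needs columns:", paste(need, collapse = ", ")))
  if (nrow(table) == 0L) abort("Empty method table.")
  if (anyNA(table$automated) || anyNA(table$manual))
    abort("Unpaired rows: automated and manual must both be present.")
  if (length(unique(table$subregion)) < 3L)
    abort("Need at least 3 subregions.")

  safe_shapiro <- function(x) {
    if (length(unique(x)) < 3L || length(x) < 3L || length(x) > 5000L)
      return(tibble(statistic = NA_real_, p.value = NA_real_))
    s <- shapiro.test(x)
    tibble(statistic = unname(s$statistic), p.value = s$p.value)
  }
  shapiro <- bind_rows(
    mutate(safe_shapiro(table$automated), variable = "automated"),
    mutate(safe_shapiro(table$manual), variable = "manual"),
    mutate(safe_shapiro(table$manual - table$automated),
           variable = "difference")) %>%
    select("variable", "statistic", "p.value")

  d <- table$manual - table$automated
  wilcoxon <- if (all(d == 0)) {
    list(statistic = c(V = 0), p.value = 1, degenerate = TRUE,
         method = "all-zero differences")
  } else {
    w <- suppressWarnings(wilcox.test(table$automated, table$manual,
                                      paired = TRUE, exact = FALSE))
    list(statistic = w$statistic, p.value = w$p.value, degenerate = FALSE,
         method = w$method)
  }

  sp_part <- suppressWarnings(
    cor.test(table$automated, table$manual, method = "spearman",
             exact = FALSE))
  means <- table %>% group_by(.data$subregion) %>%
    summarise(automated = mean(.data$automated),
              manual = mean(.data$manual), .groups = "drop")
  sp_sub <- suppressWarnings(
    cor.test(means$automated, means$manual, method = "spearman",
             exact = FALSE))

  kr_auto <- kruskal.test(table$automated, factor(table$subregion))
  kr_man <- kruskal.test(table$manual, factor(table$subregion))
  kruskal <- tibble(
    variable = c("automated", "manual"),
    statistic = c(unname(kr_auto$statistic), unname(kr_man$statistic)),
    df = c(unname(kr_auto$parameter), unname(kr_man$parameter)),
    p.value = c(kr_auto$p.value, kr_man$p.value))

  dunn <- bind_rows(
    mutate(dunn_test(table$automated, table$subregion), variable = "automated"),
    mutate(dunn_test(table$manual, table$subregion), variable = "manual")) %>%
    select("variable", dplyr::everything())

  descriptives <- table %>%
    tidyr::pivot_longer(c("automated", "manual"), names_to = "method",
                        values_to = "count") %>%
    group_by(.data$method, .data$subregion) %>%
    summarise(describe_by(.data$count), .groups = "drop")

  structure(list(shapiro = shapiro, wilcoxon = wilcoxon,
                 spearman_subregion = sp_sub, spearman_partition = sp_part,
                 kruskal = kruskal, dunn = dunn,
                 descriptives = descriptives, n_partitions = nrow(table)),
            class = "method_stats")
}

#' @export
print.method_stats <- function(x, ...) {
  cat(sprintf("<method_stats> %d paired partitions\n", x$n_partitions))
  cat(sprintf("Paired Wilcoxon: V = %g, p = %.3g%s\n",
              unname(x$wilcoxon$statistic), x$wilcoxon$p.value,
              if (isTRUE(x$wilcoxon$degenerate)) " (degenerate)" else ""))
  cat(sprintf("Spearman (subregion means): r = %.3f, p = %.3g\n",
              unname(x$spearman_subregion$estimate),
              x$spearman_subregion$p.value))
  cat(sprintf("Spearman (partitions): r = %.3f, p = %.3g\n",
              unname(x$spearman_partition$estimate),
              x$spearman_partition$p.value))
  cat("Kruskal-Wallis by subregion:\n"); print(x$kruskal)
  invisible(x)
}

#' @method tidy method_stats
#' @export
tidy.method_stats <- function(x, ...) {
  bind_rows(
    tibble(test = paste0("shapiro_", x$shapiro$variable),
           statistic = x$shapiro$statistic, p.value = x$shapiro$p.value),
    tibble(test = "wilcoxon_paired",
           statistic = unname(x$wilcoxon$statistic),
           p.value = x$wilcoxon$p.value),
    tibble(test = "spearman_subregion",
           statistic = unname(x$spearman_subregion$estimate),
           p.value = x$spearman_subregion$p.value),
    tibble(test = "spearman_partition",
           statistic = unname(x$spearman_partition$estimate),
           p.value = x$spearman_partition$p.value),
    tibble(test = paste0("kruskal_", x$kruskal$variable),
           statistic = x$kruskal$statistic, p.value = x$kruskal$p.value))
}

#' @method glance method_stats
#' @export
glance.method_stats <- function(x, ...) {
  tibble(n_partitions = x$n_partitions,
         spearman_partition = unname(x$spearman_partition$estimate),
         spearman_subregion = unname(x$spearman_subregion$estimate),
         wilcoxon_p = x$wilcoxon$p.value,
         kruskal_p_automated = x$kruskal$p.value[1],
         kruskal_p_manual = x$kruskal$p.value[2])
}
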