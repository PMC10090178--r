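#' Segmentation parameters
#'
#' @param diameter_px Expected cell diameter in pixels. The pipeline default
#'   is 24 px (18 um at 0.75 um/px), the best-performing setting of the
#'   diameter pilot sweep. `NULL` requests a flexible (auto-estimated)
#'   diameter.
#' @param backend `"classical"` (the deterministic watershed backend shipped
#'   here) or `"model"` (an external pretrained generalist segmentation
#'   model registered via `options(nisslcount.model_backend = <function>)`).
#' @param extra Named list of backend-specific thresholds, passed through
#'   verbatim and recorded in provenance.
#' @param seed RNG seed recorded in provenance (the classical backend is
#'   fully deterministic and ignores it).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(diameter_px = 24,
                                backend = c("classical", "model"),
                                extra = list(), seed = NULL) {
  if (!is.null(diameter_px)) stopifnot_scalar_pos(diameter_px, "diameter_px")
  backend <- match.arg(backend)
  structure(list(diameter_px = diameter_px, backend = backend,
                 extra = extra, seed = seed),
            class = "segmentation_params")
}

new_instance_map <- function(labels, provenance) {
  labels <- relabel_contiguous(labels)
  structure(list(labels = labels,
                 n_instances = max(labels),
                 provenance = provenance),
            class = "instance_map")
}

#' Relabel an instance map contiguously
#'
#' Maps the positive labels of an integer label image onto 1..n, preserving
#' label order and pixel sets.
#'
#' @param labels Integer matrix, 0 = background.
#' @return Integer matrix with positive labels exactly `1..n`.
#' @export
relabel_contiguous <- function(labels) {
  pos <- labels > 0L
  if (!any(pos)) return(matrix(0L, nrow(labels), ncol(labels)))
  u <- sort(unique(labels[pos]))
  remap <- integer(max(u)); remap[u] <- seq_along(u)
  out <- matrix(0L, nrow(labels), ncol(labels))
  out[pos] <- remap[labels[pos]]
  out
}

#' @export
print.instance_map <- function(x, ...) {
  cat(sprintf("<instance_map> %d x %d px, %d instances (backend: %s)\n",
              nrow(x$labels), ncol(x$labels), x$n_instances,
              x$provenance$backend %||% "?"))
  invisible(x)
}

#' Segment candidate neurons in a preprocessed partition
#'
#' Dispatches to the configured backend, masks the result to the partition's
#' validity mask, relabels instances contiguously and records provenance.
#' The `"model"` backend calls a user-registered function (for instance a
#' wrapper around a pretrained generalist cell-segmentation network) with
#' signature `function(partition, params)` returning an integer label
#' matrix; when none is registered an actionable error names the classical
#' fallback.
#'
#' @param partition A `partition_image` (inverted, contrast-adjusted).
#' @param params A [segmentation_params()].
#' @return An `instance_map`: integer `labels` (0 = background, instances
#'   1..n), `n_instances`, and `provenance`.
#' @export
segment_partition <- function(partition, params = segmentation_params()) {
  if (!inherits(partition, "partition_image"))
    abort("`partition` must be a partition_image.")
  labels <- switch(params$backend,
    classical = classical_segment_labels(partition, params),
    model = {
      fn <- getOption("nisslcount.model_backend")
      if (!is.function(fn))
        abort(paste0(
          "No model backend registered. Set options(nisslcount.model_backend = <function>) ",
          "or use backend = \"classical\", the deterministic fallback."))
      fn(partition, params)
    })
  labels[!partition$valid_mask] <- 0L
  new_instance_map(labels,
                   provenance = list(backend = params$backend,
                                     diameter_px = params$diameter_px,
                                     extra = params$extra,
                                     seed = params$seed))
}

#' Deterministic classical fallback segmentation
#'
#' Model-free watershed backend: Gaussian smoothing (sigma = diameter/8),
#' Otsu threshold computed on the valid pixels of the inverted image, hole
#' filling, Euclidean distance transform, and watershed splitting with the
#' peak-detection radius set to diameter/4 (so seeds are separated by about
#' half a cell diameter). With `diameter_px = NULL` the diameter is
#' estimated as twice the median distance-transform peak height of a pilot
#' pass. A low Otsu between-class separation (below 0.15 of the intensity
#' range) is treated as an empty partition.
#'
#' @inheritParams segment_partition
#' @return An `instance_map`.
#' @export
fallback_segment <- function(partition, params = segmentation_params()) {
  labels <- classical_segment_labels(partition, params)
  labels[!partition$valid_mask] <- 0L
  new_instance_map(labels,
                   provenance = list(backend = "classical",
                                     diameter_px = params$diameter_px,
                                     extra = params$extra,
                                     seed = params$seed))
}

otsu_threshold <- function(v) {
  # v in [0,1]; standard Otsu on a 256-bin histogram, returns threshold and
  # the between-class mean separation (for the emptiness guard)
  h <- tabulate(pmin(pmax(as.integer(v * 255) + 1L, 1L), 256L), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256) - 1L))
  mu_t <- mu[256]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  m0 <- mu[k] / omega[k]
  m1 <- (mu_t - mu[k]) / (1 - omega[k])
  if (!is.finite(m0) || !is.finite(m1)) return(list(t = 1, sep = 0))
  list(t = (k - 1L) / 255, sep = (m1 - m0) / 255)
}

classical_segment_labels <- function(partition, params) {
  img <- partition$image / 255
  d <- params$diameter_px
  if (is.null(d)) d <- estimate_diameter_px(partition)
  sigma <- max(d / 8, 0.5)
  sm <- as.matrix(EBImage::gblur(img, sigma = sigma))
  ot <- otsu_threshold(sm[partition$valid_mask])
  if (ot$sep < 0.15) return(matrix(0L, nrow(img), ncol(img)))
  mask <- sm > ot$t & partition$valid_mask
  mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5)
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))
  dist <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- EBImage::watershed(dist, tolerance = 1,
                           ext = max(1L, as.integer(round(d / 4))))
  matrix(as.integer(as.matrix(ws)), nrow(img), ncol(img))
}

# Flexible-diameter rule: 2 x median peak height of the distance transform,
# using a fixed-sigma pilot pass.
estimate_diameter_px <- function(partition) {
  img <- partition$image / 255
  sm <- as.matrix(EBImage::gblur(img, sigma = 3))
  ot <- otsu_threshold(sm[partition$valid_mask])
  if (ot$sep < 0.15) return(24)
  mask <- sm > ot$t & partition$valid_mask
  if (!any(mask)) return(24)
  dist <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- EBImage::watershed(dist, tolerance = 1, ext = 3)
  labs <- as.integer(as.matrix(ws))
  dv <- as.numeric(dist)
  pos <- labs > 0L
  if (!any(pos)) return(24)
  peaks <- tapply(dv[pos], labs[pos], max)
  max(2 * median(peaks), 4)
}

#' Match predicted instances to ground-truth instances by IoU
#'
#' One-to-one matching on descending intersection-over-union with a gate of
#' `iou_threshold` (default 0.5, the standard instance-detection criterion).
#' At a gate of at least 0.5 the matching is provably unique, so the greedy
#' assignment is exactly the optimal one.
#'
#' @param pred,gt Integer label matrices of equal shape.
#' @param iou_threshold Minimum IoU for a valid match.
#' @return A list: `matches` tibble (pred, gt, iou), `precision`, `recall`,
#'   `f1`, `n_pred`, `n_gt`.
#' @export
match_instances <- function(pred, gt, iou_threshold = 0.5) {
  stopifnot(all(dim(pred) == dim(gt)))
  n_pred <- length(unique(pred[pred > 0L]))
  n_gt <- length(unique(gt[gt > 0L]))
  sel <- pred > 0L & gt > 0L
  empty <- tibble(pred = integer(), gt = integer(), iou = numeric())
  if (!any(sel) || n_pred == 0L || n_gt == 0L) {
    pr <- if (n_pred) 0 else NA_real_
    rc <- if (n_gt) 0 else NA_real_
    return(list(matches = empty, precision = pr, recall = rc,
                f1 = if (n_pred && n_gt) 0 else NA_real_,
                n_pred = n_pred, n_gt = n_gt))
  }
  ov <- tibble(pred = as.integer(pred[sel]), gt = as.integer(gt[sel])) %>%
    count(.data$pred, .data$gt, name = "inter")
  area_p <- tabulate(pred[pred > 0L])
  area_g <- tabulate(gt[gt > 0L])
  ov <- mutate(ov, iou = .data$inter /
                 (area_p[.data$pred] + area_g[.data$gt] - .data$inter)) %>%
    filter(.data$iou >= iou_threshold) %>%
    arrange(dplyr::desc(.data$iou))
  used_p <- integer(0); used_g <- integer(0); keep <- logical(nrow(ov))
  for (i in seq_len(nrow(ov))) {
    if (!(ov$pred[i] %in% used_p) && !(ov$gt[i] %in% used_g)) {
      keep[i] <- TRUE
      used_p <- c(used_p, ov$pred[i]); used_g <- c(used_g, ov$gt[i])
    }
  }
  m <- ov[keep, c("pred", "gt", "iou")]
  tp <- nrow(m)
  precision <- tp / n_pred
  recall <- tp / n_gt
  f1 <- if (tp == 0) 0 else 2 * precision * recall / (precision + recall)
  list(matches = m, precision = precision, recall = recall, f1 = f1,
       n_pred = n_pred, n_gt = n_gt)
}

#' Pilot sweep over segmentation diameter settings
#'
#' Segments every partition at each candidate diameter (including the
#' flexible setting, `NA`) and tabulates instance counts; when ground-truth
#' label maps are supplied, detection precision, recall and F1 against them
#' (IoU >= 0.5 one-to-one matching) are pooled over partitions and the
#' settings are ranked by F1.
#'
#' @param partitions List of `partition_image` objects.
#' @param diameters Numeric vector of diameters in px; `NA` = flexible.
#' @param gt Optional list of ground-truth label matrices, same length.
#' @param backend Backend id passed to [segmentation_params()].
#' @return A tibble with one row per diameter: `diameter_px`,
#'   `n_instances`, and (with ground truth) `precision`, `recall`, `f1`,
#'   sorted by F1 when available.
#' @export
pilot_diameter_sweep <- function(partitions, diameters = c(NA, 23, 24, 26, 27),
                                 gt = NULL, backend = "classical") {
  if (!length(partitions)) abort("Need at least one partition.")
  if (!is.null(gt) && length(gt) != length(partitions))
    abort("`gt` must match `partitions` in length.")
  rows <- map(diameters, function(d) {
    dpx <- if (is.na(d)) NULL else d
    params <- segmentation_params(diameter_px = dpx, backend = backend)
    tp <- 0; np <- 0; ng <- 0; n_inst <- 0
    for (i in seq_along(partitions)) {
      im <- segment_partition(partitions[[i]], params)
      n_inst <- n_inst + im$n_instances
      if (!is.null(gt)) {
        mm <- match_instances(im$labels, gt[[i]])
        tp <- tp + nrow(mm$matches); np <- np + mm$n_pred; ng <- ng + mm$n_gt
      }
    }
    out <- tibble(diameter_px = d, n_instances = n_inst)
    if (!is.null(gt)) {
      precision <- if (np) tp / np else NA_real_
      recall <- if (ng) tp / ng else NA_real_
      f1 <- if (isTRUE(precision + recall > 0)) 2 * precision * recall /
        (precision + recall) else 0
      out <- mutate(out, precision = precision, recall = recall, f1 = f1)
    }
    out
  })
  res <- bind_rows(rows)
  if (!is.null(gt)) res <- arrange(res, dplyr::desc(.data$f1))
  res
}
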