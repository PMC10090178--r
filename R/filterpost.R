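#' Moment-matched ellipse fit of a pixel set
#'
#' Fits the ellipse whose second central moments match those of the pixel
#' set: each full axis length is `4 * sqrt(eigenvalue)` of the 2x2 central
#' covariance of the pixel coordinates (population denominator), the
#' classical region-moments definition. For a filled disc of radius r the
#' coordinate variance is r^2/4, so both axes recover 2r. Degenerate sets
#' (single pixel, collinear pixels) get a minor axis of 1 px.
#'
#' @param coords 2-column matrix of (row, col) pixel coordinates, >= 1 row.
#' @return List with `centroid` (row, col), `major_px`, `minor_px` (full
#'   axis lengths), `angle` (orientation of the major axis, radians).
#' @export
fit_ellipse <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) abort("Empty pixel set.")
  ctr <- colMeans(coords)
  if (nrow(coords) == 1L)
    return(list(centroid = ctr, major_px = 1, minor_px = 1, angle = 0))
  dr <- coords[, 1] - ctr[1]; dc <- coords[, 2] - ctr[2]
  n <- nrow(coords)
  crr <- sum(dr * dr) / n; ccc <- sum(dc * dc) / n; crc <- sum(dr * dc) / n
  tr <- crr + ccc
  det_ <- crr * ccc - crc * crc
  disc <- sqrt(max(tr * tr / 4 - det_, 0))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  if (minor < 1e-6) { minor <- 1; major <- max(major, 1) }
  # orientation of the major axis (angle of eigenvector for l1), measured
  # from the column axis
  angle <- if (abs(crc) < 1e-12 && crr <= ccc) 0 else
    atan2(l1 - ccc, crc)
  list(centroid = ctr, major_px = major, minor_px = minor, angle = angle)
}

#' Filtering parameters
#'
#' @param k_sd Diameter-threshold multiplier: segments with minor-axis
#'   diameter below `mean - k_sd * SD` (mean/SD over the partition's
#'   intensity-surviving segments) are removed. Default 0.75, the setting
#'   selected by the filter pilot; the piloted set was 1.0, 0.75, 0.5.
#' @param apply_edge_exclusion Remove segments touching the image border
#'   (used in vignette mode where both methods exclude edge-touching
#'   neurons). Default `FALSE`.
#' @param pixel_size_um Pixel size used to convert the minor axis to
#'   micrometres.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(k_sd = 0.75, apply_edge_exclusion = FALSE,
                          pixel_size_um = 0.75) {
  if (k_sd < 0) abort("`k_sd` must be >= 0.")
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  structure(list(k_sd = k_sd, apply_edge_exclusion = apply_edge_exclusion,
                 pixel_size_um = pixel_size_um),
            class = "filter_params")
}

#' Build the per-segment record table for an instance map
#'
#' One row per instance with a persistent id (the instance label), pixel
#' count, mean inverted gray value, moment-ellipse axes, minor-axis diameter
#' in micrometres, border contact, and the kept/removed bookkeeping columns.
#' Ids stay stable through every filtering pass and output file.
#'
#' @param instances An `instance_map` (or integer label matrix).
#' @param partition The `partition_image` the instances came from.
#' @param pixel_size_um Pixel size; defaults to the partition's.
#' @return A tibble of segment records.
#' @export
segment_records <- function(instances, partition,
                            pixel_size_um = partition$pixel_size_um) {
  labels <- if (inherits(instances, "instance_map")) instances$labels else instances
  stopifnot(all(dim(labels) == dim(partition$image)))
  pos <- which(labels > 0L)
  if (!length(pos)) {
    return(tibble(id = integer(), pixel_count = integer(),
                  mean_gray = numeric(), row = numeric(), col = numeric(),
                  major_px = numeric(), minor_px = numeric(),
                  angle = numeric(), diameter_um = numeric(),
                  touches_edge = logical(), status = character(),
                  removal_reason = character()))
  }
  lab <- labels[pos]
  nr <- nrow(labels)
  ri <- (pos - 1L) %% nr + 1L
  ci <- (pos - 1L) %/% nr + 1L
  g <- as.numeric(partition$image[pos])
  ids <- sort(unique(lab))
  f <- factor(lab, levels = ids)
  npix <- as.integer(table(f))
  sums <- rowsum(cbind(g, ri, ci, ri * ri, ci * ci, ri * ci), f)
  mean_gray <- sums[, 1] / npix
  mr <- sums[, 2] / npix; mc <- sums[, 3] / npix
  crr <- sums[, 4] / npix - mr^2
  ccc <- sums[, 5] / npix - mc^2
  crc <- sums[, 6] / npix - mr * mc
  tr <- crr + ccc
  disc <- sqrt(pmax(tr^2 / 4 - (crr * ccc - crc^2), 0))
  l1 <- tr / 2 + disc; l2 <- pmax(tr / 2 - disc, 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  deg <- minor < 1e-6
  minor[deg] <- 1; major[deg] <- pmax(major[deg], 1)
  angle <- ifelse(abs(crc) < 1e-12 & crr <= ccc, 0, atan2(l1 - ccc, crc))
  on_edge <- ri == 1L | ri == nr | ci == 1L | ci == ncol(labels)
  edge_ids <- unique(lab[on_edge])
  tibble(id = as.integer(ids), pixel_count = npix,
         mean_gray = unname(mean_gray),
         row = unname(mr), col = unname(mc),
         major_px = unname(major), minor_px = unname(minor),
         angle = unname(angle), diameter_um = unname(minor) * pixel_size_um,
         touches_edge = ids %in% edge_ids,
         status = "kept", removal_reason = "none")
}

#' Intensity filter: drop segments fainter than the partition mean
#'
#' The threshold is the mean inverted gray value over the partition's valid
#' pixels (tissue plus background). On the inverted image weakly stained
#' material -- extracellular space -- falls below it; segments whose mean
#' gray is strictly below the threshold are marked removed with reason
#' `"intensity"`. The boundary uses strict inequality: a segment exactly at
#' the threshold is kept.
#'
#' @param records Segment-record tibble from [segment_records()].
#' @param partition The `partition_image` (for the threshold).
#' @return The records with updated `status`/`removal_reason`; the threshold
#'   is attached as attribute `intensity_threshold`.
#' @export
intensity_filter <- function(records, partition) {
  if (!any(partition$valid_mask)) abort("Partition has an empty valid mask.")
  thr <- mean(partition$image[partition$valid_mask])
  hit <- records$status == "kept" & records$mean_gray < thr
  records$status[hit] <- "removed"
  records$removal_reason[hit] <- "intensity"
  attr(records, "intensity_threshold") <- thr
  records
}

#' Diameter filter: drop segments below mean - k.SD of the minor axis
#'
#' Over the records surviving the intensity filter, computes the mean and
#' sample standard deviation (n - 1 denominator) of the minor-axis diameter
#' in micrometres, then removes records strictly below `mean - k_sd * SD`.
#' No upper threshold is applied, so overlapping neurons segmented as one
#' object are deliberately counted as one. With fewer than two surviving
#' records the filter is a no-op with a warning. Passing `stats` freezes the
#' threshold to a previously estimated mean/SD instead of re-estimating.
#'
#' @param records Segment-record tibble (after [intensity_filter()]).
#' @param params A [filter_params()] (or a bare `k_sd` number).
#' @param stats Optional `list(mean =, sd =)` of frozen diameter statistics.
#' @return Records with updates; attributes `diameter_threshold`,
#'   `diameter_mean`, `diameter_sd` record the applied cut.
#' @export
diameter_filter <- function(records, params = filter_params(), stats = NULL) {
  k <- if (is.numeric(params)) params else params$k_sd
  surv <- records$status == "kept"
  if (is.null(stats)) {
    if (sum(surv) < 2L) {
      warn("Fewer than 2 intensity-surviving records; diameter filter skipped.")
      attr(records, "diameter_threshold") <- NA_real_
      return(records)
    }
    mu <- mean(records$diameter_um[surv])
    s <- sd(records$diameter_um[surv])
  } else {
    mu <- stats$mean; s <- stats$sd
  }
  thr <- mu - k * s
  hit <- surv & records$diameter_um < thr
  records$status[hit] <- "removed"
  records$removal_reason[hit] <- "diameter"
  attr(records, "diameter_threshold") <- thr
  attr(records, "diameter_mean") <- mu
  attr(records, "diameter_sd") <- s
  records
}

#' Edge exclusion: drop segments touching the image border
#'
#' Vignette-mode rule: any segment with a pixel on the first or last row or
#' column is removed with reason `"edge"`, matching the convention that both
#' automated and manual raters exclude neurons touching the vignette edge.
#'
#' @param records Segment-record tibble (needs the `touches_edge` column).
#' @return Updated records.
#' @export
edge_exclusion <- function(records) {
  hit <- records$status == "kept" & records$touches_edge
  records$status[hit] <- "removed"
  records$removal_reason[hit] <- "edge"
  records
}

#' Tally a filtered partition
#'
#' @param records Segment-record tibble after filtering.
#' @return One-row tibble: `n_unfiltered`, `n_kept`, `pct_kept`,
#'   `pct_excluded`, and per-reason removal counts. With zero instances the
#'   percentages are `NA`.
#' @export
partition_tally <- function(records) {
  n_unf <- nrow(records)
  n_kept <- sum(records$status == "kept")
  tibble(n_unfiltered = n_unf, n_kept = n_kept,
         pct_kept = if (n_unf) 100 * n_kept / n_unf else NA_real_,
         pct_excluded = if (n_unf) 100 * (n_unf - n_kept) / n_unf else NA_real_,
         n_removed_intensity = sum(records$removal_reason == "intensity"),
         n_removed_diameter = sum(records$removal_reason == "diameter"),
         n_removed_edge = sum(records$removal_reason == "edge"))
}

#' Tally arithmetic from bare counts
#'
#' Convenience for reproducing retained/excluded fractions from reported
#' unfiltered and kept totals.
#'
#' @param n_unfiltered,n_kept Non-negative counts, `n_kept <= n_unfiltered`.
#' @return One-row tibble as in [partition_tally()].
#' @export
tally_from_counts <- function(n_unfiltered, n_kept) {
  stopifnot(n_kept <= n_unfiltered, n_kept >= 0)
  tibble(n_unfiltered = n_unfiltered, n_kept = n_kept,
         pct_kept = if (n_unfiltered) 100 * n_kept / n_unfiltered else NA_real_,
         pct_excluded = if (n_unfiltered) 100 * (n_unfiltered - n_kept) /
           n_unfiltered else NA_real_,
         n_removed_intensity = NA_integer_, n_removed_diameter = NA_integer_,
         n_removed_edge = NA_integer_)
}

#' Run the full false-positive filter chain on an instance map
#'
#' Order: intensity threshold, then the minor-axis diameter threshold
#' (statistics computed on the intensity survivors), then edge exclusion if
#' enabled. Filters only ever remove records -- pixel sets and ids are
#' untouched -- and `n_kept` is the partition's automated neuron estimate.
#'
#' @param instances `instance_map` or integer label matrix.
#' @param partition The source `partition_image`.
#' @param params A [filter_params()].
#' @return List with `records` (full ledger, kept and removed), `tally`
#'   (one-row tibble), and `thresholds` (intensity and diameter cuts
#'   applied).
#' @export
run_filters <- function(instances, partition, params = filter_params()) {
  records <- segment_records(instances, partition,
                             pixel_size_um = params$pixel_size_um)
  thresholds <- list(intensity = NA_real_, diameter = NA_real_,
                     diameter_mean = NA_real_, diameter_sd = NA_real_)
  if (nrow(records)) {
    records <- intensity_filter(records, partition)
    thresholds$intensity <- attr(records, "intensity_threshold")
    records <- diameter_filter(records, params)
    thresholds$diameter <- attr(records, "diameter_threshold")
    thresholds$diameter_mean <- attr(records, "diameter_mean")
    thresholds$diameter_sd <- attr(records, "diameter_sd")
    if (isTRUE(params$apply_edge_exclusion)) records <- edge_exclusion(records)
  }
  list(records = records, tally = partition_tally(records),
       thresholds = thresholds)
}

#' Zero removed instances out of a label map
#'
#' @param instances `instance_map` or label matrix.
#' @param records Filtered record tibble.
#' @return Integer label matrix with removed ids set to 0 (kept ids retain
#'   their original labels).
#' @export
filtered_label_map <- function(instances, records) {
  labels <- if (inherits(instances, "instance_map")) instances$labels else instances
  removed <- records$id[records$status == "removed"]
  labels[labels %in% removed] <- 0L
  labels
}
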