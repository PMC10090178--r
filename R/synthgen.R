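#' Specify a synthetic Nissl-stained tissue slab
#'
#' A `slab_spec` describes the study conditions for one synthetic piece of
#' mounted tissue: its extent in the section plane, its mounted thickness,
#' areal densities per cell class, somal diameter distributions, and the
#' fraction of neurons planted as touching (overlapping) pairs. The defaults
#' emulate a pyramidal-layer partition: a 20.39 micrometre mounted section
#' bearing darkly stained pyramidal somata (log-normal diameter, median
#' 18 um), smaller glial cells (median 7 um), and faint extracellular blobs
#' near background intensity.
#'
#' @param width_um,height_um In-plane extent of the slab (micrometres).
#' @param thickness_um Mounted section thickness (micrometres). The default,
#'   20.39 um, is the mean measured thickness the pipeline targets.
#' @param densities Named numeric vector of areal densities in cells per
#'   square millimetre. Recognised names: `pyramidal`, `glial`, `blob`
#'   (faint extracellular artifacts).
#' @param neuron_diam_dist,glia_diam_dist Lists `list(dist = "lnorm",
#'   meanlog =, sdlog =)` giving the somal-diameter distribution per class,
#'   in micrometres. Only the log-normal family is supported.
#' @param overlap_fraction Fraction of pyramidal neurons placed as members of
#'   touching pairs (centre distance below the mean somal radius).
#' @param roi Optional 2-column matrix of polygon vertices (x, y in um)
#'   bounding cell placement; default is the full slab rectangle.
#' @param seed RNG seed; the same spec and seed reproduce the slab exactly.
#'
#' @return An object of class `slab_spec`.
#' @seealso [generate_slab()], [render_partition()]
#' @export
slab_spec <- function(width_um = 1000, height_um = 1000,
                      thickness_um = 20.39,
                      densities = c(pyramidal = 400, glial = 100, blob = 50),
                      neuron_diam_dist = list(dist = "lnorm",
                                              meanlog = log(18), sdlog = 0.15),
                      glia_diam_dist = list(dist = "lnorm",
                                            meanlog = log(7), sdlog = 0.20),
                      overlap_fraction = 0.1,
                      roi = NULL,
                      seed = NULL) {
  stopifnot_scalar_pos(width_um, "width_um")
  stopifnot_scalar_pos(height_um, "height_um")
  stopifnot_scalar_pos(thickness_um, "thickness_um")
  if (any(!is.finite(densities)) || any(densities < 0))
    abort("`densities` must be finite and non-negative.")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    abort("`overlap_fraction` must lie in [0, 1].")
  if (is.null(roi)) {
    roi <- cbind(x = c(0, width_um, width_um, 0),
                 y = c(0, 0, height_um, height_um))
  }
  structure(list(width_um = width_um, height_um = height_um,
                 thickness_um = thickness_um,
                 densities = densities,
                 neuron_diam_dist = neuron_diam_dist,
                 glia_diam_dist = glia_diam_dist,
                 overlap_fraction = overlap_fraction,
                 roi = roi, seed = seed),
            class = "slab_spec")
}

sample_diam <- function(n, dd) {
  if (!identical(dd$dist, "lnorm"))
    abort("Only log-normal diameter distributions are supported.")
  rlnorm(n, meanlog = dd$meanlog, sdlog = dd$sdlog)
}

# Rejection-sample n points uniformly inside a polygon.
sample_in_polygon <- function(n, roi) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  bx <- range(roi[, 1]); by <- range(roi[, 2])
  out_x <- numeric(0); out_y <- numeric(0)
  frac <- max(polygon_area(roi) / ((bx[2] - bx[1]) * (by[2] - by[1])), 1e-3)
  while (length(out_x) < n) {
    m <- ceiling((n - length(out_x)) / frac * 1.2) + 16L
    cx <- runif(m, bx[1], bx[2]); cy <- runif(m, by[1], by[2])
    keep <- points_in_polygon(cx, cy, roi)
    out_x <- c(out_x, cx[keep]); out_y <- c(out_y, cy[keep])
  }
  cbind(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

#' Generate a synthetic 3D tissue slab with exact ground truth
#'
#' Places cells by homogeneous Poisson processes (one per class) uniformly in
#' the spec's ROI polygon and through the mounted thickness. A configurable
#' fraction of pyramidal neurons is planted as touching pairs whose centre
#' distance is below the mean somal radius, emulating overlapping neuron
#' clusters. Each pyramidal cell carries a nucleolus point, placed uniformly
#' in the equatorial disc of half the somal radius so that the nucleolus
#' depth profile stays exactly uniform through the section -- the sampling
#' assumption of the optical fractionator. Per-cell rendering attributes
#' (aspect ratio in \[1, 1.6\], orientation, stain intensity) are drawn here
#' so that rendering is reproducible from the slab alone.
#'
#' @param spec A [slab_spec()].
#' @return An object of class `ground_truth_3d`: a list with `cells` (a
#'   tibble: id, class, x/y/z um, diameter um, aspect, angle, gray, nucleolus
#'   coordinates), the `roi` polygon, slab extents, and `true_neuron_count`
#'   (pyramidal cells whose nucleolus lies inside the ROI).
#' @export
generate_slab <- function(spec) {
  if (!inherits(spec, "slab_spec")) abort("`spec` must be a slab_spec.")
  with_seed(spec$seed, {
    area_mm2 <- polygon_area(spec$roi) / 1e6
    dens <- spec$densities
    classes <- list()

    n_pyr <- if (isTRUE(dens[["pyramidal"]] > 0))
      rpois(1L, dens[["pyramidal"]] * area_mm2) else 0L
    if (n_pyr > 0) {
      n_pair_members <- 2L * floor(spec$overlap_fraction * n_pyr / 2)
      n_primary <- n_pyr - n_pair_members / 2L
      pos <- sample_in_polygon(n_primary, spec$roi)
      x <- pos[, 1]; y <- pos[, 2]
      if (n_pair_members > 0) {
        anchors <- seq_len(n_pair_members / 2L)
        rbar <- exp(spec$neuron_diam_dist$meanlog) / 2
        d <- runif(length(anchors), 0.5, 0.99) * rbar
        th <- runif(length(anchors), 0, 2 * pi)
        x <- c(x, x[anchors] + d * cos(th))
        y <- c(y, y[anchors] + d * sin(th))
      }
      classes$pyramidal <- tibble(
        class = "pyramidal", x_um = x, y_um = y,
        z_um = runif(length(x), 0, spec$thickness_um),
        diameter_um = sample_diam(length(x), spec$neuron_diam_dist),
        aspect = runif(length(x), 1.0, 1.6),
        angle = runif(length(x), 0, pi),
        gray = pmin(pmax(rnorm(length(x), 90, 12), 40), 150))
    }

    n_gli <- if (isTRUE(dens[["glial"]] > 0))
      rpois(1L, dens[["glial"]] * area_mm2) else 0L
    if (n_gli > 0) {
      pos <- sample_in_polygon(n_gli, spec$roi)
      classes$glial <- tibble(
        class = "glial", x_um = pos[, 1], y_um = pos[, 2],
        z_um = runif(n_gli, 0, spec$thickness_um),
        diameter_um = sample_diam(n_gli, spec$glia_diam_dist),
        aspect = runif(n_gli, 1.0, 1.4),
        angle = runif(n_gli, 0, pi),
        gray = pmin(pmax(rnorm(n_gli, 130, 10), 100), 170))
    }

    n_blob <- if (!is.na(dens["blob"]) && isTRUE(dens[["blob"]] > 0))
      rpois(1L, dens[["blob"]] * area_mm2) else 0L
    if (n_blob > 0) {
      pos <- sample_in_polygon(n_blob, spec$roi)
      classes$blob <- tibble(
        class = "blob", x_um = pos[, 1], y_um = pos[, 2],
        z_um = runif(n_blob, 0, spec$thickness_um),
        diameter_um = runif(n_blob, 5, 12),
        aspect = runif(n_blob, 1.0, 2.0),
        angle = runif(n_blob, 0, pi),
        gray = pmin(rnorm(n_blob, 192, 3), 198))
    }

    cells <- bind_rows(classes)
    if (nrow(cells) == 0L) {
      cells <- tibble(class = character(), x_um = numeric(), y_um = numeric(),
                      z_um = numeric(), diameter_um = numeric(),
                      aspect = numeric(), angle = numeric(), gray = numeric())
    }

    # Nucleolus: uniform in the equatorial disc of radius r/2 (pyramidal only).
    r2 <- ifelse(cells$class == "pyramidal", cells$diameter_um / 4, NA_real_)
    u <- sqrt(runif(nrow(cells))) * r2
    th <- runif(nrow(cells), 0, 2 * pi)
    cells$nucl_x_um <- cells$x_um + u * cos(th)
    cells$nucl_y_um <- cells$y_um + u * sin(th)
    cells$nucl_z_um <- ifelse(cells$class == "pyramidal", cells$z_um, NA_real_)
    cells <- mutate(cells, id = row_number()) %>%
      select("id", dplyr::everything())

    pyr <- filter(cells, .data$class == "pyramidal")
    tnc <- if (nrow(pyr)) sum(points_in_polygon(pyr$nucl_x_um, pyr$nucl_y_um,
                                                spec$roi)) else 0L

    structure(list(cells = cells, roi = spec$roi,
                   width_um = spec$width_um, height_um = spec$height_um,
                   thickness_um = spec$thickness_um,
                   true_neuron_count = as.integer(tnc),
                   spec = spec),
              class = "ground_truth_3d")
  })
}

#' @export
print.ground_truth_3d <- function(x, ...) {
  cat(sprintf("<ground_truth_3d> %g x %g x %g um, %d cells (%d pyramidal in ROI)\n",
              x$width_um, x$height_um, x$thickness_um,
              nrow(x$cells), x$true_neuron_count))
  invisible(x)
}

# Pixel indices of a filled ellipse, optionally clipped to the image frame.
# Centre in 1-based pixel-centre coordinates; a/b semi-axes in px.
ellipse_pixels <- function(nr, nc, cr, cc, a, b, angle) {
  r_lo <- max(1L, as.integer(floor(cr - a)))
  r_hi <- min(nr, as.integer(ceiling(cr + a)))
  c_lo <- max(1L, as.integer(floor(cc - a)))
  c_hi <- min(nc, as.integer(ceiling(cc + a)))
  if (r_lo > r_hi || c_lo > c_hi) return(integer(0))
  rr <- r_lo:r_hi
  cols <- c_lo:c_hi
  dr <- rr - cr; dc <- cols - cc
  DR <- matrix(dr, nrow = length(rr), ncol = length(cols))
  DC <- matrix(dc, nrow = length(rr), ncol = length(cols), byrow = TRUE)
  u <- DC * cos(angle) + DR * sin(angle)
  v <- -DC * sin(angle) + DR * cos(angle)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside)
  if (!length(idx)) return(integer(0))
  ri <- rr[(idx - 1L) %% length(rr) + 1L]
  ci <- cols[(idx - 1L) %/% length(rr) + 1L]
  (ci - 1L) * nr + ri
}

#' Render a 2D Nissl-like partition image from a slab
#'
#' Projects the slab onto a single focal plane. Pyramidal somata away from
#' the cut faces are drawn as filled ellipses at their full minor-axis
#' diameter; somata within a fifth of their radius of the top or bottom cut
#' face are rendered as small "neuron profile" discs -- the cap cross-section
#' `2 sqrt(h (2r - h))` at cap height `h = max(face distance, 0.05 r)` -- and
#' flagged out of plane, as are cells clipped by the image border. Glia and faint extracellular blobs are drawn
#' full size. Somata are darkly stained on a light background (pre-inversion
#' 8-bit gray); additive Gaussian noise emulates digitization.
#'
#' @param slab A `ground_truth_3d` from [generate_slab()].
#' @param focal_center_um Depth of the focal plane (default mid-thickness).
#' @param depth_of_field_um Imaged depth around the focal plane (um).
#' @param pixel_size_um Pixel size (um per pixel); default 0.75.
#' @param noise_sd Gaussian noise standard deviation in gray levels.
#' @param background_gray Background gray level (pre-inversion, light).
#' @param seed RNG seed for the noise field.
#'
#' @return A `rendered_partition`: list with `image` (8-bit matrix, dark
#'   somata on light background), `gt_labels` (integer instance map),
#'   `gt_cells` (tibble: label, cell id, rendered class in
#'   neuron/profile/glia/blob, in-plane flag, true and drawn diameters,
#'   centroid in px) and `pixel_size_um`.
#' @export
render_partition <- function(slab, focal_center_um = slab$thickness_um / 2,
                             depth_of_field_um = 8,
                             pixel_size_um = 0.75,
                             noise_sd = 5, background_gray = 200,
                             seed = NULL) {
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  if (focal_center_um < 0 || focal_center_um > slab$thickness_um)
    abort("`focal_center_um` must lie inside the slab thickness.")
  p <- pixel_size_um
  nr <- as.integer(ceiling(slab$height_um / p))
  nc <- as.integer(ceiling(slab$width_um / p))
  img <- matrix(background_gray, nr, nc)
  labels <- matrix(0L, nr, nc)

  cells <- slab$cells
  t_um <- slab$thickness_um
  rows <- list()
  if (nrow(cells)) {
    # Draw faint artifacts first, then glia, profiles, and neurons on top.
    r <- cells$diameter_um / 2
    face_dist <- pmin(cells$z_um, t_um - cells$z_um)
    is_profile <- cells$class == "pyramidal" & face_dist < 0.2 * r
    band <- abs(cells$z_um - focal_center_um) <= r + depth_of_field_um / 2
    drawn <- band | cells$class != "pyramidal"
    ord <- order(match(cells$class, c("blob", "glial", "pyramidal")),
                 !is_profile)
    lab <- 0L
    for (i in ord) {
      if (!drawn[i]) next
      ci <- cells[i, ]
      cr <- (slab$height_um - ci$y_um) / p + 0.5
      cc <- ci$x_um / p + 0.5
      if (is_profile[i]) {
        hh <- max(face_dist[i], 0.05 * r[i])
        rad <- sqrt(hh * (2 * r[i] - hh))
        a <- rad / p; b <- rad / p
        drawn_diam <- 2 * rad
        rclass <- "profile"
      } else {
        b <- r[i] / p
        a <- ci$aspect * b
        drawn_diam <- ci$diameter_um
        rclass <- switch(ci$class, pyramidal = "neuron",
                         glial = "glia", blob = "blob")
      }
      px <- ellipse_pixels(nr, nc, cr, cc, a, b, ci$angle)
      if (!length(px)) next
      # border-clipped neurons keep their class but are not whole in-plane
      # somata; they are excluded from the in-plane denominator
      touches <- (ci$x_um - a * p < 0) || (ci$x_um + a * p > slab$width_um) ||
        (ci$y_um - a * p < 0) || (ci$y_um + a * p > slab$height_um)
      lab <- lab + 1L
      img[px] <- ci$gray
      labels[px] <- lab
      rows[[lab]] <- tibble(label = lab, cell_id = ci$id,
                            render_class = rclass,
                            in_plane = rclass == "neuron" && !touches,
                            diameter_um = ci$diameter_um,
                            drawn_diameter_um = drawn_diam,
                            row_px = cr, col_px = cc)
    }
  }
  gt_cells <- if (length(rows)) bind_rows(rows) else
    tibble(label = integer(), cell_id = integer(), render_class = character(),
           in_plane = logical(), diameter_um = numeric(),
           drawn_diameter_um = numeric(), row_px = numeric(),
           col_px = numeric())

  # Drop instances fully overpainted by later cells, relabel contiguously.
  present <- sort(unique(labels[labels > 0L]))
  if (nrow(gt_cells) && length(present) < nrow(gt_cells)) {
    remap <- integer(max(gt_cells$label)); remap[present] <- seq_along(present)
    keepix <- labels > 0L
    labels[keepix] <- remap[labels[keepix]]
    gt_cells <- gt_cells %>% filter(.data$label %in% present) %>%
      mutate(label = remap[.data$label])
  }

  with_seed(seed, {
    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
  })
  img <- matrix(as.integer(round(clip255(img))), nr, nc)

  structure(list(image = img, gt_labels = labels, gt_cells = gt_cells,
                 pixel_size_um = p, background_gray = background_gray,
                 focal_center_um = focal_center_um,
                 depth_of_field_um = depth_of_field_um),
            class = "rendered_partition")
}

#' @export
print.rendered_partition <- function(x, ...) {
  cat(sprintf("<rendered_partition> %d x %d px @ %g um/px, %d instances (%d in-plane neurons)\n",
              nrow(x$image), ncol(x$image), x$pixel_size_um,
              nrow(x$gt_cells), sum(x$gt_cells$in_plane)))
  invisible(x)
}

#' Crop a square vignette containing a minimum number of in-plane neurons
#'
#' Draws random square crops from a rendered partition until one contains at
#' least `min_neurons` in-plane pyramidal neurons (centroid inside the crop),
#' mirroring the 750 um x 750 um assessment vignettes. Instances are
#' relabeled contiguously; cells whose soma is cut by the crop border are
#' flagged out of plane.
#'
#' @param partition A `rendered_partition`.
#' @param side_um Vignette side length in micrometres (default 750).
#' @param min_neurons Minimum number of in-plane neurons required.
#' @param seed RNG seed for the crop offsets.
#' @param max_tries Attempts before giving up.
#' @return A `rendered_partition` of the cropped vignette.
#' @export
make_vignette <- function(partition, side_um = 750, min_neurons = 75,
                          seed = NULL, max_tries = 100) {
  p <- partition$pixel_size_um
  side_px <- as.integer(round(side_um / p))
  nr <- nrow(partition$image); nc <- ncol(partition$image)
  if (side_px > nr || side_px > nc)
    abort("Partition is smaller than the requested vignette.")
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      r0 <- sample.int(nr - side_px + 1L, 1L)
      c0 <- sample.int(nc - side_px + 1L, 1L)
      rows <- r0:(r0 + side_px - 1L); cols <- c0:(c0 + side_px - 1L)
      gt <- partition$gt_cells
      inside <- gt$row_px >= r0 & gt$row_px < r0 + side_px &
        gt$col_px >= c0 & gt$col_px < c0 + side_px
      n_in <- sum(gt$in_plane & inside)
      if (n_in >= min_neurons) {
        lab <- partition$gt_labels[rows, cols]
        img <- partition$image[rows, cols]
        present <- sort(unique(lab[lab > 0L]))
        remap <- integer(max(c(present, 1L))); remap[present] <- seq_along(present)
        lab[lab > 0L] <- remap[lab[lab > 0L]]
        gt2 <- gt %>% filter(.data$label %in% present) %>%
          mutate(label = remap[.data$label],
                 row_px = .data$row_px - r0 + 1, col_px = .data$col_px - c0 + 1)
        # border-cut somata are no longer whole in-plane neurons
        edge_lab <- unique(c(lab[1, ], lab[side_px, ], lab[, 1], lab[, side_px]))
        gt2 <- mutate(gt2, in_plane = .data$in_plane &
                        !(.data$label %in% edge_lab))
        out <- partition
        out$image <- img; out$gt_labels <- lab; out$gt_cells <- gt2
        return(out)
      }
    }
    abort(sprintf(
      "cannot satisfy min_neurons: no %g um crop with >= %d in-plane neurons after %d tries",
      side_um, min_neurons, max_tries))
  })
}
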