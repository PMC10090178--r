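# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Wrap a plain 8-bit matrix as a pipeline-ready partition (full-frame mask).
as_test_partition <- function(img, pixel_size_um = 0.75, label = "test") {
  structure(list(image = img,
                 valid_mask = matrix(TRUE, nrow(img), ncol(img)),
                 polygon = NULL, label = label,
                 pixel_size_um = pixel_size_um, meta = list()),
            class = "partition_image")
}

# Paint a filled disc into an image matrix (in place), returning the image.
draw_disc <- function(img, cr, cc, r, value) {
  rows <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  cols <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  img[(rows - cr)^2 + (cols - cc)^2 <= r^2] <- value
  img
}

# Pixel coordinates of a filled disc, as an (row, col) matrix.
disc_coords <- function(cr, cc, r) {
  g <- expand.grid(row = (cr - r - 2):(cr + r + 2),
                   col = (cc - r - 2):(cc + r + 2))
  g <- g[(g$row - cr)^2 + (g$col - cc)^2 <= r^2, ]
  as.matrix(g)
}

# A standard default-condition partition used by the filter-recovery and
# separability checks: default slab_spec densities on a 600 um square.
default_test_partition <- function(seed) {
  spec <- slab_spec(width_um = 600, height_um = 600, seed = seed)
  slab <- generate_slab(spec)
  rp <- render_partition(slab, seed = seed + 7)
  list(slab = slab, rendered = rp, partition = as_partition_image(rp))
}

# Join filter records with the synthgen class ledger.
records_with_classes <- function(records, rendered) {
  dplyr::left_join(records, rendered$gt_cells, by = c(id = "label"))
}

# A ground-truth slab built directly from a cell table (bypasses Poisson
# placement; used for hand-placed stereology and rendering oracles).
manual_slab <- function(cells, width_um, height_um, thickness_um = 20.39,
                        roi = NULL) {
  if (is.null(roi))
    roi <- cbind(c(0, width_um, width_um, 0), c(0, 0, height_um, height_um))
  defaults <- tibble::tibble(
    id = seq_len(nrow(cells)), class = "pyramidal",
    z_um = thickness_um / 2, aspect = 1, angle = 0, gray = 90)
  for (nm in names(defaults))
    if (!nm %in% names(cells)) cells[[nm]] <- defaults[[nm]]
  if (!"nucl_x_um" %in% names(cells)) cells$nucl_x_um <- cells$x_um
  if (!"nucl_y_um" %in% names(cells)) cells$nucl_y_um <- cells$y_um
  if (!"nucl_z_um" %in% names(cells)) cells$nucl_z_um <- cells$z_um
  pyr <- cells[cells$class == "pyramidal", ]
  tnc <- sum(nisslcount:::points_in_polygon(pyr$nucl_x_um, pyr$nucl_y_um, roi))
  structure(list(cells = cells, roi = roi, width_um = width_um,
                 height_um = height_um, thickness_um = thickness_um,
                 true_neuron_count = as.integer(tnc), spec = NULL),
            class = "ground_truth_3d")
}

# Independent boundary jitter for mask-agreement tests: every jittered mask
# (auto or rater) is an iid morphological perturbation of the truth, so all
# pairwise Dice scores share one distribution.
jitter_mask <- function(labels, seed) {
  set.seed(seed)
  m <- EBImage::Image((labels > 0) * 1)
  k <- EBImage::makeBrush(3, "disc")
  out <- switch(sample(3, 1),
                as.matrix(EBImage::dilate(m, k)),
                as.matrix(EBImage::erode(m, k)),
                as.matrix(m))
  out > 0.5
}
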