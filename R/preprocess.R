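#' Convert a raw slide image to 8-bit grayscale
#'
#' RGB input is collapsed with the Rec.601 luma weights (0.299, 0.587,
#' 0.114). Inputs with a dynamic range beyond 8 bits are rescaled linearly
#' by their min-max range onto \[0, 255\]; doubles in \[0, 1\] (as returned
#' by [tiff::readTIFF()]) are scaled by 255; 8-bit input passes through.
#'
#' @param img A matrix (grayscale) or an array with 3 channels (RGB).
#' @return An integer matrix with values in 0..255.
#' @export
to_8bit_gray <- function(img) {
  if (is.array(img) && length(dim(img)) == 3L) {
    if (dim(img)[3] < 3L) abort("Unsupported channel count.")
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  } else if (!is.matrix(img)) {
    abort("`img` must be a matrix or a 3-channel array.")
  }
  mx <- max(img); mn <- min(img)
  if (is.double(img) && mx <= 1 && mn >= 0) {
    img <- img * 255
  } else if (mx > 255) {
    if (mx > mn) img <- (img - mn) / (mx - mn) * 255
    else img <- img / 65535 * 255   # constant high-depth image: scale by depth
  }
  matrix(as.integer(round(clip255(img))), nrow(img), ncol(img))
}

#' Invert an 8-bit image (v -> 255 - v)
#'
#' With a mask, only pixels inside the mask are inverted; the rest are left
#' untouched. Inversion makes the dark Nissl-stained somata bright, which is
#' the orientation the segmentation and the intensity filter work in.
#'
#' @param img 8-bit matrix.
#' @param mask Optional logical matrix of the same shape.
#' @return Matrix of the same shape.
#' @export
invert_img <- function(img, mask = NULL) {
  if (any(img < 0 | img > 255)) abort("`img` must be 8-bit (0..255).")
  if (is.null(mask)) return(255L - img)
  out <- img
  out[mask] <- 255L - img[mask]
  out
}

#' Automatic linear contrast stretch
#'
#' Maps the `saturate_frac` lower and upper intensity quantiles (computed
#' over the masked pixels) to 0 and 255 with clipping, the conventional
#' "auto contrast/brightness" of interactive image-analysis programs whose
#' default per-side saturation (0.35 percent) is also the default here.
#' Constant images are returned unchanged.
#'
#' @param img 8-bit matrix.
#' @param saturate_frac Fraction of pixels saturated at each end; in
#'   \[0, 0.5).
#' @param mask Optional logical matrix; statistics and the stretch are
#'   restricted to mask-true pixels.
#' @return Matrix of the same shape.
#' @export
autocontrast <- function(img, saturate_frac = 0.0035, mask = NULL) {
  if (saturate_frac < 0 || saturate_frac >= 0.5)
    abort("`saturate_frac` must lie in [0, 0.5).")
  v <- if (is.null(mask)) as.numeric(img) else as.numeric(img[mask])
  if (!length(v)) abort("Empty mask.")
  lo <- as.numeric(quantile(v, saturate_frac, names = FALSE))
  hi <- as.numeric(quantile(v, 1 - saturate_frac, names = FALSE))
  if (hi <= lo) return(img)
  stretch <- function(x) as.integer(round(clip255((x - lo) * 255 / (hi - lo))))
  if (is.null(mask)) {
    matrix(stretch(img), nrow(img), ncol(img))
  } else {
    out <- img
    out[mask] <- stretch(img[mask])
    out
  }
}

#' Rasterize a polygon into a pixel mask (even-odd rule)
#'
#' Scanline fill: a pixel belongs to the mask when its centre is inside the
#' polygon under the even-odd (crossing-number) rule. Vertices are given as
#' a 2-column (row, col) matrix in 1-based pixel-centre coordinates.
#'
#' @param vertices 2-column matrix of (row, col) vertices.
#' @param dim Integer vector `c(nrow, ncol)` of the target mask.
#' @return Logical matrix.
#' @export
rasterize_polygon <- function(vertices, dim) {
  nr <- dim[1]; nc <- dim[2]
  mask <- matrix(FALSE, nr, nc)
  r <- vertices[, 1]; c_ <- vertices[, 2]
  n <- length(r)
  j <- c(n, seq_len(n - 1L))
  for (i in seq_len(nr)) {
    y <- i
    xs <- numeric(0)
    for (k in seq_len(n)) {
      r1 <- r[j[k]]; r2 <- r[k]
      if ((r1 > y) != (r2 > y)) {
        xs <- c(xs, c_[j[k]] + (y - r1) / (r2 - r1) * (c_[k] - c_[j[k]]))
      }
    }
    if (length(xs)) {
      xs <- sort(xs)
      cross_left <- findInterval(seq_len(nc) - 1e-9, xs)
      mask[i, ] <- (cross_left %% 2L) == 1L
    }
  }
  mask
}

#' Crop one partition out of a slide using an ROI polygon
#'
#' Crops the polygon's bounding box and rasterizes the polygon interior
#' (even-odd rule) as the validity mask. Pixels outside the mask carry the
#' fill value 0 and are excluded from every downstream statistic.
#'
#' @param img 8-bit grayscale matrix (see [to_8bit_gray()]).
#' @param polygon 2-column (row, col) vertex matrix in 1-based pixel
#'   coordinates, at least 3 vertices, nonzero area.
#' @param label Subregion label (e.g. "CA1").
#' @param pixel_size_um Pixel size in micrometres.
#' @return A `partition_image`: list with `image`, `valid_mask`, `polygon`
#'   (in cropped coordinates), `label`, `pixel_size_um`.
#' @export
crop_partition <- function(img, polygon, label = "", pixel_size_um = 0.75) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) abort("Polygon needs at least 3 vertices.")
  if (polygon_area(polygon) <= 0) abort("Degenerate polygon (area 0).")
  r_lo <- max(1L, floor(min(polygon[, 1]))); r_hi <- min(nrow(img), ceiling(max(polygon[, 1])))
  c_lo <- max(1L, floor(min(polygon[, 2]))); c_hi <- min(ncol(img), ceiling(max(polygon[, 2])))
  if (r_lo > r_hi || c_lo > c_hi) abort("Polygon lies outside the image.")
  crop <- img[r_lo:r_hi, c_lo:c_hi, drop = FALSE]
  poly_c <- cbind(polygon[, 1] - r_lo + 1, polygon[, 2] - c_lo + 1)
  mask <- rasterize_polygon(poly_c, dim(crop))
  if (!any(mask)) abort("Polygon lies outside the image.")
  crop[!mask] <- 0L
  structure(list(image = crop, valid_mask = mask, polygon = poly_c,
                 label = label, pixel_size_um = pixel_size_um,
                 meta = list()),
            class = "partition_image")
}

#' Full preprocessing chain for one partition
#'
#' Runs the pipeline order used throughout: 8-bit conversion, polygon crop,
#' inversion (inside the mask), then auto-contrast (inside the mask).
#' Outside-mask pixels are fixed at 0 on the inverted image so the ROI
#' boundary cannot spawn spurious segments.
#'
#' @inheritParams crop_partition
#' @param saturate_frac Auto-contrast saturation per side.
#' @return A `partition_image` whose `image` is inverted and
#'   contrast-adjusted; `meta$steps` records the order applied.
#' @export
preprocess_partition <- function(img, polygon, label = "",
                                 pixel_size_um = 0.75,
                                 saturate_frac = 0.0035) {
  g <- to_8bit_gray(img)
  part <- crop_partition(g, polygon, label, pixel_size_um)
  part$image <- invert_img(part$image, part$valid_mask)
  part$image[!part$valid_mask] <- 0L
  part$image <- autocontrast(part$image, saturate_frac, part$valid_mask)
  part$meta$steps <- c("to_8bit_gray", "crop", "invert", "autocontrast")
  part$meta$saturate_frac <- saturate_frac
  part
}

#' Convert a synthetic rendered partition to a pipeline-ready partition
#'
#' Applies the same inversion + auto-contrast chain as
#' [preprocess_partition()] with a full-frame validity mask.
#'
#' @param rendered A `rendered_partition` from [render_partition()].
#' @param label Subregion label to attach.
#' @param saturate_frac Auto-contrast saturation per side.
#' @return A `partition_image`.
#' @export
as_partition_image <- function(rendered, label = "synthetic",
                               saturate_frac = 0.0035) {
  nr <- nrow(rendered$image); nc <- ncol(rendered$image)
  poly <- cbind(c(0.5, 0.5, nr + 0.5, nr + 0.5),
                c(0.5, nc + 0.5, nc + 0.5, 0.5))
  mask <- matrix(TRUE, nr, nc)
  img <- invert_img(rendered$image)
  img <- autocontrast(img, saturate_frac)
  structure(list(image = img, valid_mask = mask, polygon = poly,
                 label = label, pixel_size_um = rendered$pixel_size_um,
                 meta = list(steps = c("invert", "autocontrast"),
                             saturate_frac = saturate_frac)),
            class = "partition_image")
}

#' @export
print.partition_image <- function(x, ...) {
  cat(sprintf("<partition_image> '%s' %d x %d px @ %g um/px (%.1f%% valid)\n",
              x$label, nrow(x$image), ncol(x$image), x$pixel_size_um,
              100 * mean(x$valid_mask)))
  invisible(x)
}
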