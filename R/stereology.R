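#' Optical-fractionator sampling parameters
#'
#' Defaults follow the validated counting design: 50 um x 50 um counting
#' frames, a 10 um disector, two 3 um guard zones at the section's top and
#' bottom, a section sampling fraction of 1, and an average of 10 counting
#' frames per region (the grid spacing is derived from the ROI area unless
#' given explicitly).
#'
#' @param frame_w_um,frame_h_um Counting-frame dimensions (um).
#' @param disector_h_um Disector height h (um).
#' @param guard_um Guard-zone height at each face (um).
#' @param ssf Section sampling fraction in (0, 1].
#' @param target_frames Desired average number of frames per ROI; used to
#'   derive the grid spacing as `sqrt(roi_area / target_frames)`.
#' @param grid_spacing_um Explicit grid spacing (um), overriding
#'   `target_frames`.
#' @param t_bar_method `"q_weighted"` (number-weighted mean thickness, the
#'   common stereology-software convention) or `"arithmetic"`.
#' @return An object of class `fractionator_params`.
#' @export
fractionator_params <- function(frame_w_um = 50, frame_h_um = 50,
                                disector_h_um = 10, guard_um = 3,
                                ssf = 1, target_frames = 10,
                                grid_spacing_um = NULL,
                                t_bar_method = c("q_weighted", "arithmetic")) {
  stopifnot_scalar_pos(frame_w_um, "frame_w_um")
  stopifnot_scalar_pos(frame_h_um, "frame_h_um")
  stopifnot_scalar_pos(disector_h_um, "disector_h_um")
  if (guard_um < 0) abort("`guard_um` must be >= 0.")
  if (ssf <= 0 || ssf > 1) abort("`ssf` must lie in (0, 1].")
  structure(list(frame_w_um = frame_w_um, frame_h_um = frame_h_um,
                 disector_h_um = disector_h_um, guard_um = guard_um,
                 ssf = ssf, target_frames = target_frames,
                 grid_spacing_um = grid_spacing_um,
                 t_bar_method = match.arg(t_bar_method)),
            class = "fractionator_params")
}

#' Place counting frames by systematic uniform random sampling
#'
#' Lays a square grid of spacing `s` (given, or derived from the ROI area
#' and the target frame count) over the plane with a single uniform random
#' offset in `[0, s)^2`, and places one counting frame at every grid node
#' whose node point falls inside the ROI polygon. The area sampling
#' fraction is `asf = frame_w * frame_h / s^2`.
#'
#' @param roi 2-column matrix of ROI polygon vertices (x, y in um).
#' @param params A [fractionator_params()].
#' @param offset Optional numeric length-2 offset in um (for reproducing a
#'   particular grid); default draws one uniformly.
#' @return List: `frames` tibble (x0, y0 frame origins), `spacing`, `asf`,
#'   `offset`.
#' @export
place_frames <- function(roi, params = fractionator_params(), offset = NULL) {
  roi <- as.matrix(roi)
  area <- polygon_area(roi)
  if (area <= 0) abort("ROI area must be positive.")
  s <- params$grid_spacing_um %||% sqrt(area / params$target_frames)
  if (s < max(params$frame_w_um, params$frame_h_um))
    abort("Grid spacing is smaller than the counting frame.")
  if (is.null(offset)) offset <- runif(2, 0, s)
  bx <- range(roi[, 1]); by <- range(roi[, 2])
  kx <- seq(floor((bx[1] - s - offset[1]) / s), ceiling((bx[2] - offset[1]) / s))
  ky <- seq(floor((by[1] - s - offset[2]) / s), ceiling((by[2] - offset[2]) / s))
  gx <- offset[1] + kx * s
  gy <- offset[2] + ky * s
  nodes <- expand.grid(x0 = gx, y0 = gy)
  inside <- points_in_polygon(nodes$x0, nodes$y0, roi)
  frames <- as_tibble(nodes[inside, , drop = FALSE])
  list(frames = frames, spacing = s,
       asf = params$frame_w_um * params$frame_h_um / s^2,
       offset = offset)
}

#' Count nucleoli in one counting frame (disector rule)
#'
#' Counts pyramidal-cell nucleolus points inside the unbiased counting
#' frame and the disector. The classic red exclusion lines (left and
#' bottom, with extensions) reduce, for point-like nucleoli, to a half-open
#' frame: x in (x0, x0 + w], y in [y0, y0 + h), so under an exhaustive
#' tiling every point is counted in exactly one frame. In depth, a point is
#' counted when z lies in [guard, guard + disector height). The local
#' tissue thickness is measured at the frame centre (constant by default; a
#' slab may carry a `thickness_fun(x, y)` field).
#'
#' @param frame Length-2 numeric (x0, y0) or one-row tibble with x0, y0.
#' @param slab A `ground_truth_3d`.
#' @param params A [fractionator_params()].
#' @return One-row tibble: `x0`, `y0`, `Q`, `t_um`.
#' @export
count_frame <- function(frame, slab, params = fractionator_params()) {
  if (is.data.frame(frame)) frame <- c(frame$x0[1], frame$y0[1])
  x0 <- frame[1]; y0 <- frame[2]
  w <- params$frame_w_um; h <- params$frame_h_um
  g <- params$guard_um; hd <- params$disector_h_um
  cells <- slab$cells
  pyr <- cells$class == "pyramidal"
  Q <- sum(pyr &
             cells$nucl_x_um > x0 & cells$nucl_x_um <= x0 + w &
             cells$nucl_y_um >= y0 & cells$nucl_y_um < y0 + h &
             cells$nucl_z_um >= g & cells$nucl_z_um < g + hd,
           na.rm = TRUE)
  t_um <- if (is.function(slab$thickness_fun))
    slab$thickness_fun(x0 + w / 2, y0 + h / 2) else slab$thickness_um
  tibble(x0 = x0, y0 = y0, Q = as.integer(Q), t_um = t_um)
}

#' The optical fractionator estimate
#'
#' Computes `N = sum(Q) * (t_bar / h) * (1 / asf) * (1 / ssf)`, with
#' `t_bar` the Q-weighted mean of the per-frame thickness measurements
#' (arithmetic mean as fallback when no neuron was counted, or on request).
#'
#' @param frames Tibble of [count_frame()] results (columns Q, t_um).
#' @param params A [fractionator_params()].
#' @param asf Area sampling fraction from [place_frames()].
#' @return Object of class `fractionator_estimate`: `sum_Q`, `t_bar_um`,
#'   `h_um`, `asf`, `ssf`, `n_frames`, `N`.
#' @export
fractionator_estimate <- function(frames, params, asf) {
  if (nrow(frames) < 1L) abort("Need at least one counting frame.")
  if (params$disector_h_um <= 0) abort("Disector height must be positive.")
  if (asf <= 0) abort("`asf` must be positive.")
  sum_q <- sum(frames$Q)
  t_bar <- if (sum_q > 0 && params$t_bar_method == "q_weighted")
    weighted.mean(frames$t_um, frames$Q) else mean(frames$t_um)
  N <- sum_q * (t_bar / params$disector_h_um) * (1 / asf) * (1 / params$ssf)
  structure(list(sum_Q = sum_q, t_bar_um = t_bar,
                 h_um = params$disector_h_um, asf = asf, ssf = params$ssf,
                 n_frames = nrow(frames), N = N),
            class = "fractionator_estimate")
}

#' @export
print.fractionator_estimate <- function(x, ...) {
  cat(sprintf(
    "<fractionator_estimate> N = %.1f  (sum Q = %d over %d frames, t = %.2f um, h = %g um, asf = %.4g, ssf = %g)\n",
    x$N, x$sum_Q, x$n_frames, x$t_bar_um, x$h_um, x$asf, x$ssf))
  invisible(x)
}

#' @method tidy fractionator_estimate
#' @export
tidy.fractionator_estimate <- function(x, ...) {
  tibble(sum_Q = x$sum_Q, t_bar_um = x$t_bar_um, h_um = x$h_um,
         asf = x$asf, ssf = x$ssf, n_frames = x$n_frames, N = x$N)
}

#' @method glance fractionator_estimate
#' @export
glance.fractionator_estimate <- function(x, ...) tidy(x)

#' Replicate in-silico stereology runs over a slab
#'
#' Repeats frame placement (independent uniform grid offsets), disector
#' counting and the fractionator estimate, returning the per-replicate
#' estimates. The mean over replicates is the Monte-Carlo check of the
#' estimator's unbiasedness against the slab's exact ground truth.
#'
#' @param slab A `ground_truth_3d`.
#' @param roi ROI polygon (x, y um); defaults to the slab's own ROI.
#' @param params A [fractionator_params()].
#' @param n_replicates Number of independent grid offsets.
#' @param seed RNG seed.
#' @return Object of class `stereology_run`: `replicates` tibble (rep,
#'   n_frames, sum_Q, t_bar_um, N), `asf`, `true_count`, `mean_N`, `sd_N`.
#' @export
run_stereology <- function(slab, roi = slab$roi,
                           params = fractionator_params(),
                           n_replicates = 1, seed = NULL) {
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  if (2 * params$guard_um + params$disector_h_um > slab$thickness_um + 1e-9)
    abort("Guards + disector exceed the slab thickness.")
  # ground truth against the counting ROI (may be interior to the slab)
  pyr <- filter(slab$cells, .data$class == "pyramidal")
  true_count <- if (nrow(pyr))
    sum(points_in_polygon(pyr$nucl_x_um, pyr$nucl_y_um, as.matrix(roi)))
  else 0L
  with_seed(seed, {
    reps <- map(seq_len(n_replicates), function(i) {
      pl <- place_frames(roi, params)
      if (nrow(pl$frames) == 0L)
        return(tibble(rep = i, n_frames = 0L, sum_Q = 0L,
                      t_bar_um = NA_real_, N = 0, asf = pl$asf))
      fr <- bind_rows(map(seq_len(nrow(pl$frames)), function(k)
        count_frame(pl$frames[k, ], slab, params)))
      est <- fractionator_estimate(fr, params, pl$asf)
      tibble(rep = i, n_frames = est$n_frames, sum_Q = est$sum_Q,
             t_bar_um = est$t_bar_um, N = est$N, asf = est$asf)
    })
    replicates <- bind_rows(reps)
    structure(list(replicates = replicates,
                   asf = replicates$asf[1],
                   params = params,
                   true_count = as.integer(true_count),
                   mean_N = mean(replicates$N),
                   sd_N = sd(replicates$N)),
              class = "stereology_run")
  })
}

#' @export
print.stereology_run <- function(x, ...) {
  cat(sprintf(
    "<stereology_run> %d replicate(s): mean N = %.1f (sd %.1f), true count = %s\n",
    nrow(x$replicates), x$mean_N,
    if (is.na(x$sd_N)) 0 else x$sd_N,
    x$true_count %||% "unknown"))
  invisible(x)
}

#' @method tidy stereology_run
#' @export
tidy.stereology_run <- function(x, ...) x$replicates

#' @method glance stereology_run
#' @export
glance.stereology_run <- function(x, ...) {
  tibble(n_replicates = nrow(x$replicates), mean_N = x$mean_N,
         sd_N = x$sd_N, true_count = x$true_count %||% NA_integer_,
         rel_error = if (!is.null(x$true_count) && x$true_count > 0)
           (x$mean_N - x$true_count) / x$true_count else NA_real_)
}
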