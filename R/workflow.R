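#' Default run configuration
#'
#' All pipeline thresholds are configuration, never hard-coded: 24 px
#' segmentation diameter, mean - 0.75 SD diameter cut, 50 um counting
#' frames, 10 um disector, 3 um guards, ssf 1, 0.75 um pixels, 0.35%
#' auto-contrast saturation.
#'
#' @return Nested named list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    outdir = "nisslcount-run",
    pixel_size_um = 0.75,
    synth = list(width_um = 1000, height_um = 1000, thickness_um = 20.39,
                 densities = c(pyramidal = 400, glial = 100, blob = 50),
                 overlap_fraction = 0.1, n_partitions = 1L),
    preprocess = list(saturate_frac = 0.0035),
    segment = list(diameter_px = 24, backend = "classical"),
    filter = list(k_sd = 0.75, apply_edge_exclusion = FALSE),
    stereology = list(frame_w_um = 50, frame_h_um = 50, disector_h_um = 10,
                      guard_um = 3, ssf = 1, target_frames = 10)
  )
}

#' Read a run configuration (YAML or JSON), merged over the defaults
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file; `NULL` returns the
#'   defaults.
#' @return Configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  modifyList(cfg, user)
}

#' Generate synthetic slabs and partition images on disk
#'
#' Writes, per partition: the rendered image (8-bit TIFF), the ground-truth
#' instance label map (16-bit TIFF), the per-cell ground-truth ledger (CSV),
#' the ROI polygon (JSON) and a provenance sidecar (JSON with config hash,
#' seed and versions).
#'
#' @param config Configuration list (see [default_run_config()]).
#' @return Invisibly, a tibble with one row per partition and the paths
#'   written.
#' @export
run_synth <- function(config = default_run_config()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  sy <- config$synth
  rows <- map(seq_len(sy$n_partitions), function(i) {
    seed_i <- config$seed + i
    spec <- slab_spec(width_um = sy$width_um, height_um = sy$height_um,
                      thickness_um = sy$thickness_um,
                      densities = unlist(sy$densities),
                      overlap_fraction = sy$overlap_fraction,
                      seed = seed_i)
    slab <- generate_slab(spec)
    rp <- render_partition(slab, pixel_size_um = config$pixel_size_um,
                           seed = seed_i + 10000L)
    base <- file.path(config$outdir, sprintf("partition_%03d", i))
    write_image_tiff(rp$image, paste0(base, ".tif"))
    write_labels_tiff(rp$gt_labels, paste0(base, "_labels.tif"))
    write.csv(slab$cells, paste0(base, "_cells.csv"), row.names = FALSE)
    nrp <- nrow(rp$image); ncp <- ncol(rp$image)
    write_roi_json(cbind(c(1, 1, nrp, nrp), c(1, ncp, ncp, 1)),
                   label = sprintf("synthetic_%03d", i),
                   pixel_size_um = config$pixel_size_um,
                   path = paste0(base, "_roi.json"))
    write_sidecar(paste0(base, "_sidecar.json"), config = config,
                  seed = seed_i, stage = "synth",
                  true_neuron_count = slab$true_neuron_count)
    tibble(partition = i, image = paste0(base, ".tif"),
           labels = paste0(base, "_labels.tif"),
           cells = paste0(base, "_cells.csv"),
           roi = paste0(base, "_roi.json"),
           true_neuron_count = slab$true_neuron_count)
  })
  invisible(bind_rows(rows))
}

#' Run preprocess, segmentation and filtering over partitions on disk
#'
#' For every `partition_*.tif` + `partition_*_roi.json` pair under
#' `config$outdir`: preprocess, segment with the configured backend, run
#' the filter chain, and write the per-segment ledger CSV plus a pooled
#' tallies CSV. `n_kept` per partition is the automated neuron estimate.
#'
#' @param config Configuration list.
#' @return Tibble of per-partition tallies (also written to
#'   `tallies.csv`).
#' @export
run_estimate <- function(config = default_run_config()) {
  imgs <- sort(list.files(config$outdir, "^partition_[0-9]+\\.tif$",
                          full.names = TRUE))
  if (!length(imgs))
    abort(sprintf("No partition TIFFs found under '%s'; run run_synth() or point `outdir` at existing partitions.",
                  config$outdir))
  rows <- map(imgs, function(img_path) {
    base <- sub("\\.tif$", "", img_path)
    roi_path <- paste0(base, "_roi.json")
    if (!file.exists(roi_path))
      abort(sprintf("Missing ROI JSON for '%s' (expected '%s').",
                    img_path, roi_path))
    roi <- read_roi_json(roi_path)
    img <- read_slide_tiff(img_path)
    part <- preprocess_partition(img, roi$vertices, label = roi$label,
                                 pixel_size_um = roi$pixel_size_um,
                                 saturate_frac = config$preprocess$saturate_frac)
    params <- segmentation_params(diameter_px = config$segment$diameter_px,
                                  backend = config$segment$backend,
                                  seed = config$seed)
    im <- segment_partition(part, params)
    fl <- run_filters(im, part,
                      filter_params(k_sd = config$filter$k_sd,
                                    apply_edge_exclusion =
                                      config$filter$apply_edge_exclusion,
                                    pixel_size_um = roi$pixel_size_um))
    write_ledger_csv(fl$records, basename(base), paste0(base, "_ledger.csv"))
    mutate(fl$tally, partition_id = basename(base), label = roi$label) %>%
      select("partition_id", "label", dplyr::everything())
  })
  tallies <- bind_rows(rows)
  write.csv(tallies, file.path(config$outdir, "tallies.csv"),
            row.names = FALSE)
  write_sidecar(file.path(config$outdir, "estimate_sidecar.json"),
                config = config, seed = config$seed, stage = "estimate",
                n_partitions = nrow(tallies),
                total_kept = sum(tallies$n_kept))
  tallies
}

#' Run the method-comparison statistics from a method table CSV
#'
#' @param config Configuration list; expects
#'   `config$method_table` to name a CSV with columns `partition_id`,
#'   `subregion`, `automated`, `manual`.
#' @return The `method_stats` object; a JSON report and scatter figure are
#'   written next to the table.
#' @export
run_compare <- function(config) {
  path <- config$method_table
  if (is.null(path) || !file.exists(path))
    abort("`config$method_table` must name an existing CSV.")
  table <- as_tibble(read.csv(path))
  ms <- method_stats(table)
  out <- sub("\\.csv$", "_stats.json", path)
  jsonlite::write_json(
    list(glance = glance(ms), tests = tidy(ms),
         descriptives = ms$descriptives, dunn = ms$dunn),
    out, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  fig <- sub("\\.csv$", "_scatter.png", path)
  ggplot2::ggsave(fig, plot_method_table(table), width = 6, height = 5,
                  dpi = 150)
  inform(sprintf("Wrote %s and %s", out, fig))
  ms
}
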