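## End-to-end orchestration: simulate or load a field grid, segment nuclei
## per field, build the consensus virtual slide, segment colonies from the
## mosaic, extract features, attach spatial context, gate phases and
## markers, and write a relational CSV set joined by ids.

#' Default pipeline configuration
#'
#' A nested list of every tunable parameter, with units. Override entries
#' by name, or load from YAML/JSON with [read_pipeline_config()].
#'
#' @param ... Named overrides merged (recursively for sub-lists) into the
#'   defaults.
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    grid = list(nx = 2, ny = 2, field_w = 330, field_h = 330, overlap = 60),
    pixel_size = 1,                       # um / px
    channels = list(dna = "dna", edu = "edu", ph3 = "ph3", marker = "marker"),
    scene = scene_params(),               # used when simulating input
    noise = list(enabled = TRUE, read_sd = 2),
    nuclei = nuclei_params(),
    colony = list(sigma = 8, min_area_um2 = 2000),
    max_cell_diameter_um = 15,
    layers = list(n_layers = 3, cell_diameter_um = NA),  # NA: median observed
    windows = list(w_um = 250, h_um = 192, class_edges = NULL),
    bins = list(k = 8),
    gating = list(B = 1000, level = 0.95, seed = 1, dna_gate_sd = 3),
    seed = 1)
  over <- list(...)
  merge_in <- function(base, o) {
    for (nm in names(o)) {
      if (is.list(o[[nm]]) && is.list(base[[nm]]) && !is.null(base[[nm]]))
        base[[nm]] <- merge_in(base[[nm]], o[[nm]])
      else base[[nm]] <- o[[nm]]
    }
    base
  }
  cfg <- merge_in(cfg, over)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys mirror
#'   [pipeline_config()].
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- raw$scene
  raw$scene <- NULL
  cfg <- do.call(pipeline_config, raw)
  if (!is.null(sc)) {
    if (!is.null(sc$phase_props)) sc$phase_props <- unlist(sc$phase_props)
    if (!is.null(sc$periphery_phase_props))
      sc$periphery_phase_props <- unlist(sc$periphery_phase_props)
    if (!is.null(sc$layer1_phase_props))
      sc$layer1_phase_props <- unlist(sc$layer1_phase_props)
    cfg$scene <- do.call(scene_params, sc)
  }
  cfg
}

#' Run the colony analysis pipeline
#'
#' Input is either a list of [field_image()] (`fields`), a directory of
#' TIFFs written by [write_field_tiff()] (`input_dir`), or nothing, in
#' which case a synthetic scene is generated from `config$scene` and
#' rendered over `config$grid`. Stages: per-field nuclei segmentation;
#' consensus relabeling into a seamless region label matrix; colony
#' segmentation on the DNA mosaic; feature extraction; colony addressing;
#' distance-from-edge, layers, colony size classes and density windows;
#' cell-cycle gate fitting and phase calls; marker gating; equal-count
#' distance bins with percentile-bootstrap phase frequencies per bin and
#' per layer. With `output_dir` set, writes `cells.csv`, `colonies.csv`,
#' `windows.csv`, `bin_freqs.csv`, `layer_freqs.csv`, label TIFFs, and a
#' `parameters.txt` log of every parameter and fitted threshold actually
#' used. Reruns with the same config and seed are deterministic.
#'
#' @param config A [pipeline_config()].
#' @param fields Optional list of [field_image()].
#' @param input_dir Optional directory of `.tif` + `.json` field files.
#' @param output_dir Optional output directory (created if needed).
#' @return List with `cells`, `colonies`, `windows`, `bin_freqs`,
#'   `layer_freqs`, `gates`, `region_labels`, `colony_labels`, `mapping`,
#'   `grid`, and (when simulated) `scene`.
#' @export
run_pipeline <- function(config = pipeline_config(), fields = NULL,
                         input_dir = NULL, output_dir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  g <- config$grid
  grid <- grid_spec(g$nx, g$ny, g$field_w, g$field_h, g$overlap,
                    config$pixel_size)
  scene <- NULL
  if (is.null(fields) && !is.null(input_dir)) {
    paths <- sort(list.files(input_dir, pattern = "\\.tiff?$",
                             full.names = TRUE))
    if (!length(paths)) stop("no TIFF fields found in ", input_dir)
    fields <- lapply(paths, read_field_tiff)
  }
  if (is.null(fields)) {
    scene <- generate_colony_scene(config$scene, seed = config$seed)
    fields <- render_fields(scene, grid, channels = unlist(config$channels),
                            noise = isTRUE(config$noise$enabled),
                            read_sd = config$noise$read_sd)
  }
  dna_ch <- config$channels$dna
  if (is.null(dna_ch) || is.null(fields[[1]]$channels[[dna_ch]]))
    stop("required DNA channel '", dna_ch %||% "dna",
         "' is missing from the input fields")

  ## --- per-field nuclei segmentation + consensus ---
  field_labels <- lapply(fields, segment_nuclei, channel = dna_ch,
                         params = config$nuclei)
  cons <- consensus_segmentation(field_labels, grid,
                                 config$max_cell_diameter_um)

  ## --- colony segmentation on the mosaic ---
  mosaic_dna <- mosaic_fields(fields, grid, channel = dna_ch)
  colony_labels <- segment_colonies(mosaic_dna, sigma = config$colony$sigma,
                                    min_area = config$colony$min_area_um2,
                                    pixel_size = config$pixel_size)
  colonies <- colony_features(colony_labels, config$pixel_size)

  ## --- features over the consensus labels ---
  mosaics <- lapply(config$channels, function(ch)
    mosaic_fields(fields, grid, channel = ch))
  feats <- extract_features(cons$labels, mosaics, config$pixel_size)
  addr <- assign_addresses(cons$labels, colony_labels, config$pixel_size)
  cells <- merge(addr, feats, by.x = "global_label", by.y = "label")
  cells <- merge(cells, cons$mapping[, c("global_label", "field_x", "field_y",
                                         "source_label")], by = "global_label")
  names(cells)[names(cells) == "colony_id"] <- "colony_id"
  cells$x_um <- cells$centroid_x_um; cells$y_um <- cells$centroid_y_um

  ## --- spatial context ---
  cells$distance_um <- distance_from_edge(
    colony_labels, cells[, c("x_um", "y_um")], config$pixel_size)
  d_layer <- config$layers$cell_diameter_um
  if (is.na(d_layer)) d_layer <- stats::median(cells$equiv_diameter_um)
  cells$layer <- assign_layers(cells$distance_um, d_layer,
                               config$layers$n_layers)
  cells$size_class <- colonies$size_class[match(cells$colony_id,
                                                colonies$colony_id)]
  dw <- density_windows(cells, config$windows$w_um, config$windows$h_um,
                        config$windows$class_edges)
  cells$window_id <- dw$cell_window$window_id
  cells$density_class <- dw$cell_window$density_class

  ## --- gating ---
  dna_int <- cells[[paste0(dna_ch, "_int")]]
  edu <- cells[[paste0(config$channels$edu, "_mean")]]
  ph3 <- cells[[paste0(config$channels$ph3, "_mean")]]
  gates <- fit_cell_cycle_gates(dna_int, edu, ph3,
                                dna_gate_sd = config$gating$dna_gate_sd)
  cells$phase <- classify_phase(dna_int, edu, ph3, gates)
  mk <- paste0(config$channels$marker, "_mean")
  thr <- marker_threshold(cells[[mk]])
  cells$marker_positive <- cells[[mk]] > thr

  ## --- binned and layered bootstrap frequencies ---
  member <- cells$phase != "unclassified"
  eb <- equal_count_bins(cells$distance_um[member],
                         min(config$bins$k, sum(member)))
  bin_freqs <- bootstrap_frequencies(droplevels(cells$phase[member]),
                                     eb$bin, B = config$gating$B,
                                     level = config$gating$level,
                                     seed = config$gating$seed)
  layer_freqs <- bootstrap_frequencies(droplevels(cells$phase[member]),
                                       as.integer(cells$layer[member]),
                                       B = config$gating$B,
                                       level = config$gating$level,
                                       seed = config$gating$seed)
  layer_freqs$layer <- levels(cells$layer)[layer_freqs$bin]

  out <- list(cells = cells, colonies = colonies, windows = dw$windows,
              bin_freqs = bin_freqs, bin_edges = eb$edges,
              layer_freqs = layer_freqs, gates = gates,
              marker_threshold = thr, cell_diameter_um = d_layer,
              region_labels = cons$labels, colony_labels = colony_labels,
              mapping = cons$mapping, grid = grid, scene = scene)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, nm) utils::write.csv(
      df, file.path(output_dir, nm), row.names = FALSE)
    wr(cells, "cells.csv"); wr(colonies, "colonies.csv")
    wr(dw$windows, "windows.csv"); wr(bin_freqs, "bin_freqs.csv")
    wr(layer_freqs, "layer_freqs.csv")
    write_label_tiff(cons$labels, file.path(output_dir, "region_labels.tif"))
    write_label_tiff(colony_labels, file.path(output_dir, "colony_labels.tif"))
    log <- c(sprintf("seed: %d", config$seed),
             sprintf("pixel_size_um: %g", config$pixel_size),
             sprintf("grid: %dx%d fields %dx%d overlap %d",
                     g$nx, g$ny, g$field_w, g$field_h, g$overlap),
             sprintf("nuclei: sigma %g method %s area [%g, %g] um2",
                     config$nuclei$sigma, config$nuclei$method,
                     config$nuclei$min_area_um2, config$nuclei$max_area_um2),
             sprintf("colony: sigma %g min_area %g um2",
                     config$colony$sigma, config$colony$min_area_um2),
             sprintf("cell_diameter_um (layers): %g", d_layer),
             sprintf("gates: 2N %.6g 4N %.6g edu %.6g ph3 %.6g marker %.6g",
                     gates$dna_2n, gates$dna_4n, gates$edu_threshold,
                     gates$ph3_threshold, thr),
             sprintf("bootstrap: B %d level %g seed %d",
                     config$gating$B, config$gating$level, config$gating$seed))
    writeLines(log, file.path(output_dir, "parameters.txt"))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
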