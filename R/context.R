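## Spatial population context: distance from colony edge, cell layers,
## colony size classes, equal-count distance bins, and local-density windows.

#' Distance of cell centroids from the colony edge
#'
#' Evaluates the Euclidean distance transform of the colony mask at each
#' centroid pixel. Outside the boundaries of any colony the distance from
#' edge is 0; within a colony it ranges from 0 up to the colony's maximum
#' edge distance.
#'
#' @param colony_labels Integer colony label matrix (rows = y).
#' @param centroids_um Two-column matrix or data frame of centroid `x`, `y`
#'   in micrometres (same frame as the labels).
#' @param pixel_size Micrometres per pixel.
#' @return Numeric vector of distances in micrometres.
#' @export
distance_from_edge <- function(colony_labels, centroids_um, pixel_size = 1) {
  p <- as.matrix(centroids_um)[, 1:2, drop = FALSE]
  if (nrow(p) == 0) return(numeric(0))
  dm <- EBImage::distmap(colony_labels > 0)
  ix <- pmin(pmax(floor(p[, 1] / pixel_size) + 1, 1), ncol(colony_labels))
  iy <- pmin(pmax(floor(p[, 2] / pixel_size) + 1, 1), nrow(colony_labels))
  as.numeric(dm[cbind(iy, ix)]) * pixel_size
}

#' Assign cells to edge-distance layers
#'
#' Distance 0 is the periphery; a distance in `((k-1) d, k d]` is cell layer
#' `k` for `k = 1..n_layers`; anything deeper is "interior".
#'
#' @param distances Distances from the colony edge in micrometres.
#' @param cell_diameter Cell diameter `d` in micrometres (the per-sample
#'   median nuclear equivalent diameter is a good choice).
#' @param n_layers Number of layers to resolve.
#' @return Factor with levels `periphery`, `layer1..layerN`, `interior`.
#' @export
assign_layers <- function(distances, cell_diameter, n_layers = 3) {
  stopifnot(cell_diameter > 0, n_layers >= 1)
  if (any(distances < 0)) stop("negative distance from edge")
  k <- ceiling(distances / cell_diameter)
  lab <- ifelse(distances == 0, "periphery",
                ifelse(k <= n_layers, paste0("layer", k), "interior"))
  factor(lab, levels = c("periphery", paste0("layer", seq_len(n_layers)),
                         "interior"))
}

#' Classify colony size from the maximum edge distance
#'
#' Small below 150 um, medium from 150 to 300 um (inclusive at both ends),
#' large above 300 um.
#'
#' @param max_edge_distance Maximum cellular distance from the colony edge
#'   to the centre, micrometres (see [colony_features()]).
#' @return Character vector in `c("small", "medium", "large")`.
#' @export
classify_colony_size <- function(max_edge_distance) {
  stopifnot(all(max_edge_distance >= 0))
  ifelse(max_edge_distance < 150, "small",
         ifelse(max_edge_distance <= 300, "medium", "large"))
}

#' Partition distances into equal-count bins
#'
#' Bin edges are the empirical quantiles of a sort-and-split of the data, so
#' bin counts differ only by ties at an edge. Duplicate edges caused by
#' massive ties are collapsed with a warning.
#'
#' @param distances Numeric values (e.g. distance from edge, micrometres).
#' @param k Number of bins; must not exceed the number of observations.
#' @return List with `edges` (length `k + 1`, first = min, last = max) and
#'   `bin` (integer bin index per observation; bin `j` spans
#'   `(edges[j], edges[j+1]]`, the first bin closed at the minimum).
#' @export
equal_count_bins <- function(distances, k) {
  n <- length(distances)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("more bins than observations")
  xs <- sort(distances)
  inner <- xs[ceiling(seq_len(k - 1) * n / k)]
  edges <- c(xs[1], inner, xs[n])
  if (anyDuplicated(edges)) {
    warning("duplicate bin edges collapsed (ties in the data)")
    edges <- unique(edges)
  }
  if (length(edges) < 2) edges <- c(edges, edges)  # all values identical
  bin <- findInterval(distances, edges[-length(edges)], left.open = TRUE,
                      rightmost.closed = FALSE)
  bin[bin == 0] <- 1L   # values at the minimum belong to the first bin
  list(edges = edges, bin = as.integer(bin))
}

#' Tile colonies into fixed-size density windows and classify them
#'
#' Each colony's bounding box (over its member cell centroids) is tiled,
#' left-to-right and top-to-bottom, into windows of `window_w` by `window_h`
#' micrometres (partial edge windows kept). Window cell counts are
#' classified low / mixed / high against two class edges; by default the
#' tertiles of the observed window counts. Every cell inherits the class of
#' its window.
#'
#' @param cells Data frame with columns `colony_id`, `x_um`, `y_um` (cells
#'   with `colony_id` 0 are ignored: windows are colony-wise).
#' @param window_w,window_h Window size in micrometres.
#' @param class_edges Optional numeric `c(low_max, mixed_max)`: counts
#'   `<= low_max` are low, `<= mixed_max` mixed, larger high. Default:
#'   tertiles of the window counts.
#' @return List with `windows` (data frame: window_id, colony_id, x0/y0/
#'   x1/y1 um half-open bounds, count, density_class) and `cell_window`
#'   (per row of `cells`: window_id and density_class, NA for periphery).
#' @export
density_windows <- function(cells, window_w = 250, window_h = 192,
                            class_edges = NULL) {
  stopifnot(window_w > 0, window_h > 0)
  win <- list(); cw_id <- rep(NA_integer_, nrow(cells))
  wid <- 0L
  for (cid in sort(unique(cells$colony_id[cells$colony_id > 0]))) {
    sel <- which(cells$colony_id == cid)
    if (!length(sel)) next
    x <- cells$x_um[sel]; y <- cells$y_um[sel]
    x0 <- min(x); y0 <- min(y)
    ix <- floor((x - x0) / window_w); iy <- floor((y - y0) / window_h)
    nx <- max(ix) + 1; ny <- max(iy) + 1
    for (jy in 0:(ny - 1)) for (jx in 0:(nx - 1)) {
      wid <- wid + 1L
      inwin <- ix == jx & iy == jy
      win[[wid]] <- data.frame(
        window_id = wid, colony_id = cid,
        x0_um = x0 + jx * window_w, y0_um = y0 + jy * window_h,
        x1_um = x0 + (jx + 1) * window_w, y1_um = y0 + (jy + 1) * window_h,
        count = sum(inwin))
      cw_id[sel[inwin]] <- wid
    }
  }
  if (!length(win))
    return(list(windows = data.frame(window_id = integer(0),
                                     colony_id = integer(0), x0_um = numeric(0),
                                     y0_um = numeric(0), x1_um = numeric(0),
                                     y1_um = numeric(0), count = integer(0),
                                     density_class = character(0)),
                cell_window = data.frame(window_id = cw_id,
                                         density_class = rep(NA_character_,
                                                             nrow(cells)))))
  windows <- do.call(rbind, win)
  if (is.null(class_edges))
    class_edges <- unname(stats::quantile(windows$count, c(1, 2) / 3, type = 1))
  windows$density_class <- ifelse(windows$count <= class_edges[1], "low",
                                  ifelse(windows$count <= class_edges[2],
                                         "mixed", "high"))
  cell_class <- windows$density_class[match(cw_id, windows$window_id)]
  list(windows = windows,
       cell_window = data.frame(window_id = cw_id, density_class = cell_class))
}
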