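## The virtual slide: region-level label matrices and cell addresses
## assembled from per-field segmentations without stitching raw pixels.
## Objects segmented in two adjacent fields are matched by pixel-space
## overlap of their region-coordinate footprints and resolved by keeping
## the larger instance.

#' Mosaic field images into one region image
#'
#' Places each field at its grid origin. In shared overlap margins the field
#' with the smaller grid index (row-major: `fy`, then `fx`) owns the pixels;
#' no blending is performed, since downstream analysis relies on label
#' consensus rather than stitched intensities.
#'
#' @param fields List of [field_image()] covering every grid position.
#' @param grid A [grid_spec()].
#' @param channel Channel name to mosaic (default: first channel).
#' @return Numeric matrix of size [region_dim()] (rows = y).
#' @export
mosaic_fields <- function(fields, grid, channel = NULL) {
  stopifnot(inherits(grid, "GridSpec"))
  idx <- field_index_map(fields, grid)
  rd <- region_dim(grid)
  out <- matrix(0, rd[2], rd[1])
  ## write in decreasing grid order so the smallest index wins overlaps
  ord <- order(vapply(fields, function(f) f$fy * grid$nx + f$fx, numeric(1)),
               decreasing = TRUE)
  for (i in ord) {
    f <- fields[[i]]
    ch <- if (is.null(channel)) f$channels[[1]] else f$channels[[channel]]
    if (is.null(ch)) stop("channel '", channel, "' missing in field (",
                          f$fx, ",", f$fy, ")")
    if (length(dim(ch)) == 3) ch <- apply(ch, c(1, 2), max)
    o <- field_origin(grid, f$fx, f$fy)
    out[o[2] + seq_len(grid$field_h), o[1] + seq_len(grid$field_w)] <- ch
  }
  out
}

## Check that every grid position is present exactly once; return lookup.
field_index_map <- function(fields, grid) {
  key <- vapply(fields, function(f) f$fy * grid$nx + f$fx, numeric(1))
  want <- 0:(grid$nx * grid$ny - 1)
  miss <- setdiff(want, key)
  if (length(miss))
    stop("missing field(s) at grid position(s): ",
         paste(sprintf("(%d,%d)", miss %% grid$nx, miss %/% grid$nx),
               collapse = ", "))
  match(want, key)
}

## Per-label pixel lists of a label matrix, as 0-based (x, y) coordinates.
label_pixels <- function(lab) {
  pos <- which(lab > 0)
  if (!length(pos)) return(list())
  split(pos, lab[pos])
}

#' Centroids of a label matrix
#'
#' @param lab Integer label matrix (rows = y, 0 = background).
#' @return Data frame with `label`, `area_px`, and 0-based pixel-centre
#'   centroids `x_px`, `y_px`.
#' @export
label_centroids <- function(lab) {
  pix <- label_pixels(lab)
  if (!length(pix))
    return(data.frame(label = integer(0), area_px = integer(0),
                      x_px = numeric(0), y_px = numeric(0)))
  h <- nrow(lab)
  out <- lapply(names(pix), function(l) {
    p <- pix[[l]]
    y <- (p - 1) %% h; x <- (p - 1) %/% h
    data.frame(label = as.integer(l), area_px = length(p),
               x_px = mean(x), y_px = mean(y))
  })
  do.call(rbind, out)
}

#' Consensus seamless segmentation across overlapping fields
#'
#' Loads every field's label matrix into region coordinates and resolves
#' objects that were segmented in more than one field. Two instances are
#' treated as the same physical object when their region-coordinate
#' footprints share at least one pixel and their centroids are within one
#' `max_cell_diameter`; of corresponding instances, the larger (by pixel
#' area) is kept, ties going to the field with the smaller grid index. The
#' rule is applied transitively, so a corner object seen by up to four
#' fields keeps its largest instance. Overlapping instances whose centroids
#' are farther apart than `max_cell_diameter` are distinct objects (touching
#' neighbours) and are both kept, earlier-written pixels winning any pixel
#' conflict. Objects touching the outer 1-px frame of the region are
#' discarded.
#'
#' For the heuristic to be seamless every cell must fit entirely inside at
#' least one field, which holds when the overlap is at least twice the
#' maximum cell diameter; a warning is issued when the grid violates this.
#'
#' @param field_labels List of integer label matrices, each with attributes
#'   `fx` and `fy` (as produced by [truth_field_labels()] or by running
#'   [segment_nuclei()] per field), or a list of lists
#'   `list(labels=, fx=, fy=)`.
#' @param grid A [grid_spec()].
#' @param max_cell_diameter Maximum cell diameter in micrometres.
#' @return A list with `labels` (region label matrix, global labels
#'   1..n) and `mapping` (data frame: global_label, field_x, field_y,
#'   source_label, area_px, centroid x/y in px and um).
#' @export
consensus_segmentation <- function(field_labels, grid, max_cell_diameter) {
  stopifnot(inherits(grid, "GridSpec"))
  max_d_px <- max_cell_diameter / grid$pixel_size
  if (grid$overlap < 2 * max_d_px)
    warning("overlap (", grid$overlap, " px) is below twice the maximum ",
            "cell diameter (", 2 * max_d_px, " px); cells may not be fully ",
            "contained in any single field")
  rd <- region_dim(grid)
  region <- matrix(0L, rd[2], rd[1])
  ## registry of accepted instances
  reg <- list()   # each: list(gid, fx, fy, src, area, cx, cy, pos)
  next_gid <- 1L

  get_lab <- function(fl) {
    if (is.list(fl) && !is.null(fl$labels)) {
      lab <- fl$labels; fx <- fl$fx; fy <- fl$fy
    } else {
      lab <- fl; fx <- attr(fl, "fx"); fy <- attr(fl, "fy")
    }
    if (is.null(fx) || is.null(fy))
      stop("field label matrices need fx/fy grid attributes")
    list(lab = lab, fx = fx, fy = fy)
  }
  ord <- order(vapply(field_labels, function(fl) {
    g <- get_lab(fl); g$fy * grid$nx + g$fx
  }, numeric(1)))

  for (i in ord) {
    g <- get_lab(field_labels[[i]])
    o <- field_origin(grid, g$fx, g$fy)
    pix <- label_pixels(g$lab)
    h <- nrow(g$lab)
    for (lname in names(pix)) {
      p <- pix[[lname]]
      ly <- (p - 1) %% h; lx <- (p - 1) %/% h
      gx <- lx + o[1]; gy <- ly + o[2]
      pos <- gy + 1 + gx * rd[2]          # linear index into region matrix
      area <- length(p)
      cx <- mean(gx); cy <- mean(gy)
      ## find existing instances whose footprint overlaps
      hit_gids <- unique(region[pos])
      hit_gids <- hit_gids[hit_gids > 0]
      corresponds <- integer(0)
      for (hg in hit_gids) {
        r <- reg[[hg]]
        if (sqrt((r$cx - cx)^2 + (r$cy - cy)^2) <= max_d_px)
          corresponds <- c(corresponds, hg)
      }
      if (length(corresponds)) {
        best_area <- max(vapply(reg[corresponds], `[[`, numeric(1), "area"))
        if (area > best_area) {
          ## new instance wins: erase all corresponding older instances
          for (hg in corresponds) {
            region[reg[[hg]]$pos] <- 0L
            reg[[hg]]$dropped <- TRUE
          }
        } else {
          next  # existing instance is at least as large; drop the new one
        }
      }
      free <- region[pos] == 0L
      region[pos[free]] <- next_gid
      reg[[next_gid]] <- list(gid = next_gid, fx = g$fx, fy = g$fy,
                              src = as.integer(lname), area = area,
                              cx = cx, cy = cy, pos = pos[free],
                              dropped = FALSE)
      next_gid <- next_gid + 1L
    }
  }

  ## discard objects touching the outer 1-px frame of the region
  border <- unique(c(region[1, ], region[rd[2], ], region[, 1], region[, rd[1]]))
  border <- border[border > 0]
  for (bg in border) {
    region[reg[[bg]]$pos] <- 0L
    reg[[bg]]$dropped <- TRUE
  }

  keep <- Filter(function(r) !r$dropped, reg)
  ## relabel 1..n in original acceptance order
  out <- matrix(0L, rd[2], rd[1])
  maps <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    r <- keep[[j]]
    out[r$pos] <- j
    maps[[j]] <- data.frame(global_label = j, field_x = r$fx, field_y = r$fy,
                            source_label = r$src, area_px = r$area,
                            centroid_x_px = r$cx, centroid_y_px = r$cy)
  }
  mapping <- if (length(maps)) do.call(rbind, maps) else
    data.frame(global_label = integer(0), field_x = integer(0),
               field_y = integer(0), source_label = integer(0),
               area_px = integer(0), centroid_x_px = numeric(0),
               centroid_y_px = numeric(0))
  mapping$centroid_x_um <- mapping$centroid_x_px * grid$pixel_size
  mapping$centroid_y_um <- mapping$centroid_y_px * grid$pixel_size
  list(labels = out, mapping = mapping)
}

#' Assign colony addresses to segmented cells
#'
#' Each cell's colony id is the colony label under its centroid pixel; a
#' centroid outside every colony mask gets colony id 0 (the periphery:
#' distance-from-edge 0). The nearest colony is also reported so peripheral
#' cells keep their context.
#'
#' @param region_labels Region cell label matrix.
#' @param colony_labels Colony label matrix of the same shape.
#' @param pixel_size Micrometres per pixel.
#' @param region Region number recorded in the output (default 1).
#' @return Data frame of cell addresses: `global_label`, `region`,
#'   centroids in px and um, `colony_id`, `nearest_colony_id`.
#' @export
assign_addresses <- function(region_labels, colony_labels, pixel_size = 1,
                             region = 1L) {
  if (!all(dim(region_labels) == dim(colony_labels)))
    stop("region_labels and colony_labels must have the same shape")
  cen <- label_centroids(region_labels)
  if (nrow(cen) == 0)
    return(data.frame(global_label = integer(0), region = integer(0),
                      centroid_x_px = numeric(0), centroid_y_px = numeric(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                      colony_id = integer(0), nearest_colony_id = integer(0)))
  iy <- pmin(pmax(round(cen$y_px) + 1, 1), nrow(colony_labels))
  ix <- pmin(pmax(round(cen$x_px) + 1, 1), ncol(colony_labels))
  cid <- colony_labels[cbind(iy, ix)]
  ## nearest colony for peripheral cells, via colony centroid distance
  ncid <- cid
  if (any(cid == 0) && any(colony_labels > 0)) {
    ccen <- label_centroids(colony_labels)
    for (i in which(cid == 0)) {
      d2 <- (ccen$x_px - cen$x_px[i])^2 + (ccen$y_px - cen$y_px[i])^2
      ncid[i] <- ccen$label[which.min(d2)]
    }
  }
  data.frame(global_label = cen$label, region = region,
             centroid_x_px = cen$x_px, centroid_y_px = cen$y_px,
             centroid_x_um = cen$x_px * pixel_size,
             centroid_y_um = cen$y_px * pixel_size,
             colony_id = as.integer(cid),
             nearest_colony_id = as.integer(ncid))
}
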