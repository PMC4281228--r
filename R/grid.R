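#' Specify a rectangular grid of overlapping imaging fields
#'
#' A `GridSpec` describes how a large region is tiled by an `nx` by `ny`
#' grid of camera fields whose neighbours share an `overlap`-pixel margin.
#' Adjacent field origins differ by `field_w - overlap` pixels in x (and the
#' analogous step in y), so the full region spans
#' `nx * (field_w - overlap) + overlap` pixels.
#'
#' All pixel coordinates in this package are 0-based, with `x` running along
#' matrix columns and `y` along matrix rows; physical position in micrometres
#' is `pixels * pixel_size`.
#'
#' @param nx,ny Number of fields along x and y (>= 1).
#' @param field_w,field_h Field width and height in pixels.
#' @param overlap Shared margin between adjacent fields, in pixels;
#'   must satisfy `0 <= overlap < min(field_w, field_h)`.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @return An object of class `GridSpec`.
#' @examples
#' g <- grid_spec(3, 3, 160, 160, overlap = 30)
#' region_dim(g)  # 420 x 420 px
#' @export
grid_spec <- function(nx, ny, field_w, field_h, overlap, pixel_size = 1) {
  stopifnot(nx >= 1, ny >= 1, field_w >= 1, field_h >= 1, pixel_size > 0)
  if (overlap < 0 || overlap >= min(field_w, field_h))
    stop("overlap must be >= 0 and smaller than the field size")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 field_w = as.integer(field_w), field_h = as.integer(field_h),
                 overlap = as.integer(overlap), pixel_size = pixel_size),
            class = "GridSpec")
}

#' @export
print.GridSpec <- function(x, ...) {
  cat(sprintf("GridSpec: %d x %d fields of %d x %d px, overlap %d px (%.3g um/px)\n",
              x$nx, x$ny, x$field_w, x$field_h, x$overlap, x$pixel_size))
  invisible(x)
}

#' Total region size implied by a grid
#'
#' @param grid A [grid_spec()].
#' @return Integer vector `c(width, height)` in pixels.
#' @export
region_dim <- function(grid) {
  stopifnot(inherits(grid, "GridSpec"))
  c(grid$nx * (grid$field_w - grid$overlap) + grid$overlap,
    grid$ny * (grid$field_h - grid$overlap) + grid$overlap)
}

#' Origin of a field in region coordinates
#'
#' @param grid A [grid_spec()].
#' @param fx,fy 0-based grid indices of the field.
#' @return `c(x0, y0)`, 0-based region pixel coordinates of the field's
#'   top-left pixel.
#' @export
field_origin <- function(grid, fx, fy) {
  stopifnot(fx >= 0, fx < grid$nx, fy >= 0, fy < grid$ny)
  c(fx * (grid$field_w - grid$overlap), fy * (grid$field_h - grid$overlap))
}

#' Convert field-local pixel coordinates to region coordinates
#'
#' Maps 0-based `(x, y)` pixel coordinates inside the field at grid position
#' `field_xy` to 0-based region pixel coordinates. The map is invertible
#' (see [to_local_coords()]); the two representations of a physical point in
#' the shared margin of adjacent fields map to the same region coordinate.
#'
#' @param field_xy `c(fx, fy)` 0-based grid indices.
#' @param local_px Numeric vector `c(x, y)` or an n-by-2 matrix of 0-based
#'   field-local pixel coordinates.
#' @param grid A [grid_spec()].
#' @return Region pixel coordinates, same shape as `local_px`.
#' @export
to_global_coords <- function(field_xy, local_px, grid) {
  p <- if (is.matrix(local_px)) local_px else matrix(local_px, ncol = 2)
  if (any(p[, 1] < 0) || any(p[, 1] > grid$field_w - 1) ||
      any(p[, 2] < 0) || any(p[, 2] > grid$field_h - 1))
    stop("local coordinates outside the field")
  o <- field_origin(grid, field_xy[1], field_xy[2])
  out <- cbind(p[, 1] + o[1], p[, 2] + o[2])
  if (is.matrix(local_px)) out else drop(out)
}

#' Convert region pixel coordinates to field-local coordinates
#'
#' @param field_xy `c(fx, fy)` 0-based grid indices.
#' @param global_px `c(x, y)` or n-by-2 matrix of 0-based region coordinates.
#' @param grid A [grid_spec()].
#' @return Field-local pixel coordinates.
#' @export
to_local_coords <- function(field_xy, global_px, grid) {
  p <- if (is.matrix(global_px)) global_px else matrix(global_px, ncol = 2)
  o <- field_origin(grid, field_xy[1], field_xy[2])
  out <- cbind(p[, 1] - o[1], p[, 2] - o[2])
  if (any(out[, 1] < 0) || any(out[, 1] > grid$field_w - 1) ||
      any(out[, 2] < 0) || any(out[, 2] > grid$field_h - 1))
    stop("region coordinates outside this field")
  if (is.matrix(global_px)) out else drop(out)
}

#' Construct a FieldImage
#'
#' One grid position's multi-channel image. Each channel is either a numeric
#' matrix (2-D image, rows = y, cols = x) or a 3-D array `[y, x, z]`
#' (a z-stack).
#'
#' @param channels Named list of matrices/arrays, all with identical y/x size.
#' @param fx,fy 0-based grid position of the field.
#' @param pixel_size Micrometres per pixel.
#' @return An object of class `FieldImage`.
#' @export
field_image <- function(channels, fx, fy, pixel_size = 1) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  d <- lapply(channels, function(ch) dim(ch)[1:2])
  if (length(unique(lapply(d, as.integer))) != 1)
    stop("all channels must share the same y/x dimensions")
  structure(list(channels = channels, fx = as.integer(fx), fy = as.integer(fy),
                 pixel_size = pixel_size),
            class = "FieldImage")
}

#' @export
print.FieldImage <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("FieldImage (%d,%d): %s; %d x %d px%s\n", x$fx, x$fy,
              paste(names(x$channels), collapse = ", "), d[2], d[1],
              if (length(d) == 3) sprintf(" x %d z", d[3]) else ""))
  invisible(x)
}
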