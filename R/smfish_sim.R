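## Synthetic single-molecule FISH z-stacks: diffraction-limited 3-D Gaussian
## point sources scattered around nuclei inside a colony, rendered over an
## overlapping field grid with a smooth across-region gain gradient, plus
## Poisson shot noise and Gaussian read noise.

#' Parameters for a synthetic smFISH region
#'
#' @param n_cells Number of cells (nuclei) in the region.
#' @param spots_per_cell Poisson mean number of mRNA spots per cell.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF sigma in x/y and z (pixels).
#'   The lateral full width at half maximum is `2.355 * psf_sigma_xy` and
#'   must be at least 1 px.
#' @param n_z Number of z planes.
#' @param background Camera background level (a.u., enters the shot noise).
#' @param colony_bg Diffuse RNA background staining inside the colony (a.u.);
#'   this is what the colony mask is derived from.
#' @param read_sd Gaussian read-noise SD (a.u.).
#' @param gain_gradient Fractional drop in illumination gain from the first
#'   to the last field column (emulates signal diminution across a wide
#'   region); each field gets a constant gain from this gradient.
#' @param amp_mean Median spot amplitude (a.u.).
#' @param min_snr If given, overrides `amp_mean` so that the 1st percentile
#'   of the log-normal amplitude distribution sits at `min_snr` times the
#'   background noise SD, i.e. essentially every generated spot has at
#'   least that signal-to-noise ratio.
#' @param amp_sdlog Log-scale SD of the log-normal spot amplitudes; the
#'   heavy lower tail produces the near-threshold spots that adaptive
#'   threshold equalization exists for.
#' @param nucleus_radius_px Nucleus radius in pixels (spots are placed in an
#'   annulus around the nucleus centre, i.e. mostly cytoplasmic).
#' @param cell_territory_px Radius within which a cell's spots are placed.
#' @param min_spot_separation_sigma Minimum separation between any two true
#'   spots, in PSF-normalized units (lateral offsets divided by
#'   `psf_sigma_xy`, axial by `psf_sigma_z`); single-molecule counting
#'   presumes diffraction-separated molecules, so closer pairs (which would
#'   fuse into one focus) are not generated.
#' @param pixel_size Micrometres per pixel.
#' @return List of class `smfish_params`.
#' @export
smfish_params <- function(n_cells = 12, spots_per_cell = 40,
                          psf_sigma_xy = 1.3, psf_sigma_z = 1.6, n_z = 9,
                          background = 20, colony_bg = 60, read_sd = 3,
                          gain_gradient = 0.3,
                          amp_mean = 150, amp_sdlog = 0.25,
                          nucleus_radius_px = 7, cell_territory_px = 14,
                          min_spot_separation_sigma = 4, pixel_size = 1,
                          min_snr = NULL) {
  if (2.355 * psf_sigma_xy < 1)
    stop("PSF width below 1 px: spots would be unresolvable")
  if (!is.null(min_snr)) {
    noise_sd <- sqrt(background + colony_bg + read_sd^2)
    amp_mean <- min_snr * noise_sd * exp(stats::qnorm(0.99) * amp_sdlog)
  }
  out <- as.list(environment())
  class(out) <- "smfish_params"
  out
}

#' Nominal signal-to-noise ratio of a parameter set
#'
#' Median spot amplitude divided by the background noise SD
#' (shot noise of background plus diffuse stain, plus read noise).
#' @param params An [smfish_params()] list.
#' @return Scalar SNR.
#' @export
smfish_snr <- function(params) {
  params$amp_mean / sqrt(params$background + params$colony_bg + params$read_sd^2)
}

## Add one 3-D Gaussian point source to a stack [y, x, z].
paint_spot <- function(stack, x, y, z, amp, sxy, sz) {
  d <- dim(stack)
  r <- ceiling(3 * sxy); rz <- ceiling(3 * sz)
  ix <- max(1, floor(x - r)):min(d[2], ceiling(x + r + 1))
  iy <- max(1, floor(y - r)):min(d[1], ceiling(y + r + 1))
  iz <- max(1, floor(z - rz)):min(d[3], ceiling(z + rz + 1))
  if (!length(ix) || !length(iy) || !length(iz)) return(stack)
  gx <- exp(-((ix - 0.5 - x)^2) / (2 * sxy^2))
  gy <- exp(-((iy - 0.5 - y)^2) / (2 * sxy^2))
  gz <- exp(-((iz - 0.5 - z)^2) / (2 * sz^2))
  add <- amp * outer(outer(gy, gx), gz)
  stack[iy, ix, iz] <- stack[iy, ix, iz] + add
  stack
}

#' Generate a synthetic smFISH region as overlapping z-stack fields
#'
#' Builds a colony occupying most of the region, places nuclei inside it,
#' scatters log-normal-amplitude diffraction-limited spots around each
#' nucleus, and renders one z-stack per grid field. Each field is a crop of
#' the same noise-free region stack multiplied by a per-field gain taken
#' from a smooth across-region gradient, then degraded with Poisson and read
#' noise. Spots falling in shared margins are listed for every field that
#' contains them.
#'
#' @param params An [smfish_params()] list.
#' @param grid A [grid_spec()] describing the field grid.
#' @param seed Integer RNG seed.
#' @param noise If `FALSE`, fields are returned noise-free.
#' @return A list with `fields` (list of [field_image()] with channel
#'   `fish`, a `[y, x, z]` array), `spots` (truth table in region pixel
#'   coordinates, sub-pixel: id, cell, x_px, y_px, z_px, amplitude),
#'   `spots_by_field` (truth per field with local coordinates; margin spots
#'   appear once per containing field), `cells` (nucleus centres, region
#'   px), `nuclei_labels` (region label matrix of nucleus discs),
#'   `colony_mask` (region logical matrix), `gains` (per-field data frame),
#'   `grid`, `params`, `seed`.
#' @export
generate_smfish_stack <- function(params = smfish_params(), grid, seed = 1,
                                  noise = TRUE) {
  stopifnot(inherits(params, "smfish_params"), inherits(grid, "GridSpec"))
  rd <- region_dim(grid)
  with_seed(seed, {
    W <- rd[1]; H <- rd[2]
    ## colony: an irregular blob centred in the region
    poly <- blob_polygon(W / 2, H / 2, 0.42 * min(W, H), rough = 0.08)
    xs <- seq_len(W) - 0.5; ys <- seq_len(H) - 0.5
    g <- expand.grid(x = xs, y = ys)
    colony_mask <- matrix(points_in_polygon(poly, g$x, g$y), H, W, byrow = TRUE)
    ## nuclei inside the colony, min separation
    nx <- numeric(0); ny <- numeric(0)
    tries <- 0L
    while (length(nx) < params$n_cells && tries < 400 * params$n_cells) {
      tries <- tries + 1L
      x <- stats::runif(1, 0, W); y <- stats::runif(1, 0, H)
      if (!points_in_polygon(poly, x, y)) next
      if (polygon_edge_distance(poly, x, y) < params$cell_territory_px * 0.8) next
      if (length(nx) && min((nx - x)^2 + (ny - y)^2) <
            (2.2 * params$nucleus_radius_px)^2) next
      nx <- c(nx, x); ny <- c(ny, y)
    }
    n_cells <- length(nx)
    if (n_cells < params$n_cells)
      warning("placed ", n_cells, " of ", params$n_cells, " nuclei")
    cells <- data.frame(cell = seq_len(n_cells), x_px = nx, y_px = ny)
    nuclei_labels <- matrix(0L, H, W)
    if (n_cells > 0) {
      for (i in seq_len(n_cells)) {
        r <- params$nucleus_radius_px
        ix <- max(1, floor(nx[i] - r)):min(W, ceiling(nx[i] + r))
        iy <- max(1, floor(ny[i] - r)):min(H, ceiling(ny[i] + r))
        X <- matrix(ix - 0.5 - nx[i], length(iy), length(ix), byrow = TRUE)
        Y <- matrix(iy - 0.5 - ny[i], length(iy), length(ix))
        sel <- X^2 + Y^2 <= r^2
        sub <- nuclei_labels[iy, ix, drop = FALSE]
        sub[sel] <- i
        nuclei_labels[iy, ix] <- sub
      }
    }
    ## spots: per cell, Poisson count, placed within the cell territory with
    ## a minimum 3-D separation (diffraction-separated molecules)
    sp <- list()
    sx <- numeric(0); sy <- numeric(0); sz <- numeric(0)
    for (i in seq_len(n_cells)) {
      k <- stats::rpois(1, params$spots_per_cell)
      if (k == 0) next
      cx <- numeric(0); cy <- numeric(0); cz <- numeric(0)
      tries <- 0L
      while (length(cx) < k && tries < 200 * k) {
        tries <- tries + 1L
        rr <- sqrt(stats::runif(1)) * params$cell_territory_px
        th <- stats::runif(1, 0, 2 * pi)
        x <- min(max(nx[i] + rr * cos(th), 1), W - 1)
        y <- min(max(ny[i] + rr * sin(th), 1), H - 1)
        z <- stats::runif(1, 2.5, params$n_z - 2.5)
        ## cytoplasm is the cell's territory: the spot must lie inside the
        ## colony and closer to its own nucleus than to any other
        if (!points_in_polygon(poly, x, y)) next
        if (n_cells > 1 &&
            min(((nx - x)^2 + (ny - y)^2)[-i]) <= (nx[i] - x)^2 + (ny[i] - y)^2)
          next
        if (length(sx) && min(((sx - x)^2 + (sy - y)^2) / params$psf_sigma_xy^2 +
                              (sz - z)^2 / params$psf_sigma_z^2) <
              params$min_spot_separation_sigma^2) next
        cx <- c(cx, x); cy <- c(cy, y); cz <- c(cz, z)
        sx <- c(sx, x); sy <- c(sy, y); sz <- c(sz, z)
      }
      if (!length(cx)) next
      sp[[i]] <- data.frame(
        cell = i, x_px = cx, y_px = cy, z_px = cz,
        amplitude = stats::rlnorm(length(cx), log(params$amp_mean),
                                  params$amp_sdlog))
    }
    spots <- if (length(sp)) do.call(rbind, sp) else
      data.frame(cell = integer(0), x_px = numeric(0), y_px = numeric(0),
                 z_px = numeric(0), amplitude = numeric(0))
    if (nrow(spots)) spots <- cbind(id = seq_len(nrow(spots)), spots)
    else spots <- cbind(data.frame(id = integer(0)), spots)

    ## noise-free region stack
    stack <- array(0, dim = c(H, W, params$n_z))
    for (z in seq_len(params$n_z))
      stack[, , z] <- stack[, , z] + colony_mask * params$colony_bg
    if (nrow(spots)) for (i in seq_len(nrow(spots)))
      stack <- paint_spot(stack, spots$x_px[i], spots$y_px[i], spots$z_px[i],
                          spots$amplitude[i], params$psf_sigma_xy,
                          params$psf_sigma_z)

    ## crop fields, apply gain gradient + noise
    gains <- expand.grid(fx = 0:(grid$nx - 1), fy = 0:(grid$ny - 1))
    gains$gain <- if (grid$nx > 1)
      1 - params$gain_gradient * gains$fx / (grid$nx - 1) else 1
    fields <- list(); sbf <- list()
    for (i in seq_len(nrow(gains))) {
      fx <- gains$fx[i]; fy <- gains$fy[i]
      o <- field_origin(grid, fx, fy)
      crop <- stack[o[2] + seq_len(grid$field_h),
                    o[1] + seq_len(grid$field_w), , drop = FALSE]
      img <- gains$gain[i] * crop + params$background
      if (noise) {
        img <- array(stats::rpois(length(img), pmax(img, 0)) +
                       stats::rnorm(length(img), 0, params$read_sd), dim(img))
      }
      fields[[i]] <- field_image(list(fish = img), fx, fy, grid$pixel_size)
      if (nrow(spots)) {
        inside <- spots$x_px >= o[1] & spots$x_px < o[1] + grid$field_w &
          spots$y_px >= o[2] & spots$y_px < o[2] + grid$field_h
        if (any(inside)) {
          loc <- spots[inside, ]
          loc$fx <- fx; loc$fy <- fy
          loc$x_local <- loc$x_px - o[1]; loc$y_local <- loc$y_px - o[2]
          sbf[[length(sbf) + 1]] <- loc
        }
      }
    }
    spots_by_field <- if (length(sbf)) do.call(rbind, sbf) else NULL
    list(fields = fields, spots = spots, spots_by_field = spots_by_field,
         cells = cells, nuclei_labels = nuclei_labels,
         colony_mask = colony_mask, gains = gains, grid = grid,
         params = params, seed = seed)
  })
}
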