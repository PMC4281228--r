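## Synthetic ground-truth scenes: clustered colonies of elliptical nuclei with
## phase-dependent DNA content, S/M marker bimodality, position-dependent
## marker expression, and per-field gain/background effects. Every downstream
## stage of the pipeline is validated against these truths.

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Parameters of a synthetic colony scene
#'
#' Defaults emulate a typical human pluripotent stem cell culture imaged at
#' 1 um/px: a few hundred ~12 um nuclei clustered into non-convex colonies,
#' with a cycling population (high S fraction), G1-enriched loosely attached
#' cells at the colony periphery, G2-enriched cells in the first cell layer,
#' and a mostly marker-positive population whose negative fraction is
#' concentrated at the periphery and in G1.
#'
#' @param n_colonies Number of colonies.
#' @param cells_per_colony Interior cells per colony.
#' @param scene_w_um,scene_h_um Scene size in micrometres.
#' @param pixel_size Micrometres per pixel used when rendering.
#' @param colony_radius_um Nominal colony radius; individual colonies vary
#'   around it and have smoothly irregular (non-convex) boundaries.
#' @param cell_diameter_um,cell_diameter_sd Mean and SD of the nuclear major
#'   axis; draws are truncated to `[7, max_cell_diameter_um]`.
#' @param max_cell_diameter_um Upper bound on any nuclear diameter; also the
#'   value analysis stages should use as "maximum cell diameter".
#' @param min_separation_um Minimum centroid separation between nuclei.
#' @param frac_peripheral Fraction of cells placed just outside the colony
#'   boundary (the "periphery" population, distance-from-edge 0).
#' @param phase_props Named probabilities for G1/S/G2/M in the colony bulk;
#'   must sum to 1.
#' @param periphery_phase_props,layer1_phase_props Phase probabilities for
#'   peripheral cells and for the first cell layer (distance from edge at
#'   most one cell diameter). Defaults plant the enrichment seen in hPS
#'   colonies: G1 at the periphery, G2 in layer 1.
#' @param dna_g1,dna_cv G1 (2N) integrated DNA intensity (a.u.) and its
#'   lognormal coefficient of variation; G2/M cells average twice `dna_g1`,
#'   S cells fall in between.
#' @param edu_low,edu_high,edu_cv Off/on modes of the S-phase (EdU) mean
#'   intensity and their lognormal spread.
#' @param ph3_low,ph3_high,ph3_cv Off/on modes of the M-phase (pH3) marker.
#' @param marker_pos,marker_neg,marker_cv Positive/negative modes of the
#'   pluripotency marker (Nanog/Oct4-like).
#' @param marker_neg_frac_g1,marker_neg_frac_other,marker_neg_frac_periphery
#'   Probability that a cell is marker-negative, by context.
#' @param colony_glow Diffuse within-colony background added to the DNA
#'   channel when rendering (a.u. per pixel); emulates cytoplasmic staining.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(n_colonies = 3, cells_per_colony = 100,
                         scene_w_um = 600, scene_h_um = 600, pixel_size = 1,
                         colony_radius_um = 110,
                         cell_diameter_um = 12, cell_diameter_sd = 1.5,
                         max_cell_diameter_um = 15, min_separation_um = 9,
                         frac_peripheral = 0.06,
                         phase_props = c(G1 = 0.45, S = 0.30, G2 = 0.20, M = 0.05),
                         periphery_phase_props = c(G1 = 0.70, S = 0.15, G2 = 0.12, M = 0.03),
                         layer1_phase_props = c(G1 = 0.33, S = 0.30, G2 = 0.32, M = 0.05),
                         dna_g1 = 5000, dna_cv = 0.12,
                         edu_low = 40, edu_high = 600, edu_cv = 0.35,
                         ph3_low = 30, ph3_high = 500, ph3_cv = 0.35,
                         marker_pos = 800, marker_neg = 60, marker_cv = 0.35,
                         marker_neg_frac_g1 = 0.10,
                         marker_neg_frac_other = 0.01,
                         marker_neg_frac_periphery = 0.63,
                         colony_glow = 10) {
  for (p in list(phase_props, periphery_phase_props, layer1_phase_props)) {
    if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("phase proportions must be 4 non-negative values summing to 1")
  }
  out <- as.list(environment())
  class(out) <- "scene_params"
  out
}

## Irregular star-shaped colony boundary: radius modulated by low-order
## Fourier modes, giving smooth, typically non-convex outlines.
blob_polygon <- function(cx, cy, r0, n_vertices = 120, rough = 0.10) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  r <- rep(1, n_vertices)
  for (k in 2:5) {
    a <- stats::rnorm(1, 0, rough / sqrt(k))
    ph <- stats::runif(1, 0, 2 * pi)
    r <- r + a * cos(k * th + ph)
  }
  r <- pmax(r, 0.35) * r0
  data.frame(x = cx + r * cos(th), y = cy + r * sin(th))
}

points_in_polygon <- function(poly, x, y) {
  mgcv::in.out(as.matrix(poly[, c("x", "y")]), cbind(x, y))
}

## Minimum distance from points to the polygon boundary (segment-wise).
polygon_edge_distance <- function(poly, x, y) {
  px <- poly$x; py <- poly$y
  qx <- c(px[-1], px[1]); qy <- c(py[-1], py[1])
  dx <- qx - px; dy <- qy - py
  len2 <- pmax(dx^2 + dy^2, 1e-12)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    t <- pmin(pmax(((x[i] - px) * dx + (y[i] - py) * dy) / len2, 0), 1)
    out[i] <- sqrt(min((x[i] - (px + t * dx))^2 + (y[i] - (py + t * dy))^2))
  }
  out
}

rlnorm_mean <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
}

#' Generate a ground-truth colony scene
#'
#' Draws colony outlines, places nuclei inside them (plus a small loosely
#' attached peripheral population), assigns each cell a cell-cycle phase
#' conditional on its spatial zone, and draws per-channel true intensities:
#' integrated DNA content (G2/M about twice G1), bimodal S-phase and M-phase
#' markers, and a pluripotency marker whose negative fraction depends on
#' phase and position. The same seed and parameters always reproduce the
#' identical truth.
#'
#' @param params A [scene_params()] list.
#' @param seed Integer RNG seed.
#' @return An object of class `SceneTruth`: a list with `cells` (data frame,
#'   one row per cell: id, colony, x/y in um, diameter, orientation, aspect,
#'   zone, true distance from colony edge, phase and channel intensities),
#'   `colonies` (list of boundary polygons in um), scene dimensions,
#'   `pixel_size`, `params` and `seed`.
#' @export
generate_colony_scene <- function(params = scene_params(), seed = 1) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(seed, {
    W <- params$scene_w_um; H <- params$scene_h_um
    ## -- colony outlines, rejection-placed so they do not overlap
    centers <- matrix(numeric(0), ncol = 3)  # cx, cy, r0
    for (i in seq_len(params$n_colonies)) {
      for (try in 1:200) {
        r0 <- params$colony_radius_um * stats::runif(1, 0.75, 1.2)
        if (2 * (1.25 * r0 + 5) >= min(W, H)) r0 <- 0.35 * min(W, H)
        margin <- min(1.25 * r0 + 5, min(W, H) / 2 - 1)
        cx <- stats::runif(1, margin, W - margin)
        cy <- stats::runif(1, margin, H - margin)
        ok <- nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
                1.25 * (centers[, 3] + r0) + 5)
        if (ok) { centers <- rbind(centers, c(cx, cy, r0)); break }
      }
    }
    if (nrow(centers) < params$n_colonies)
      stop("could not place ", params$n_colonies, " non-overlapping colonies; ",
           "reduce colony_radius_um or n_colonies")
    colonies <- lapply(seq_len(nrow(centers)), function(i)
      blob_polygon(centers[i, 1], centers[i, 2], centers[i, 3]))

    ## -- nuclei
    d_draw <- function(n) pmin(pmax(stats::rnorm(n, params$cell_diameter_um,
                                                 params$cell_diameter_sd), 7),
                               params$max_cell_diameter_um)
    cells <- list()
    id0 <- 0L
    for (ci in seq_along(colonies)) {
      poly <- colonies[[ci]]
      n_int <- params$cells_per_colony
      n_per <- max(0L, round(params$frac_peripheral * n_int))
      bx <- range(poly$x); by <- range(poly$y)
      acc_x <- numeric(0); acc_y <- numeric(0)
      ## interior cells, minimum centroid separation
      tries <- 0L
      while (length(acc_x) < n_int && tries < 200 * n_int) {
        tries <- tries + 1L
        x <- stats::runif(1, bx[1], bx[2]); y <- stats::runif(1, by[1], by[2])
        if (!points_in_polygon(poly, x, y)) next
        if (length(acc_x) &&
            min((acc_x - x)^2 + (acc_y - y)^2) < params$min_separation_um^2) next
        acc_x <- c(acc_x, x); acc_y <- c(acc_y, y)
      }
      if (length(acc_x) < n_int)
        warning("colony ", ci, ": placed ", length(acc_x), " of ",
                n_int, " cells (density too high)")
      n_int <- length(acc_x)
      zone_d <- polygon_edge_distance(poly, acc_x, acc_y)
      ## peripheral cells: just outside the boundary
      per_x <- numeric(0); per_y <- numeric(0)
      cc <- colMeans(poly[, c("x", "y")])
      while (length(per_x) < n_per) {
        v <- sample.int(nrow(poly), 1)
        dir <- c(poly$x[v] - cc[1], poly$y[v] - cc[2])
        dir <- dir / sqrt(sum(dir^2))
        off <- stats::runif(1, 2, 1.5 * params$cell_diameter_um)
        x <- poly$x[v] + off * dir[1]; y <- poly$y[v] + off * dir[2]
        if (x < 2 || y < 2 || x > W - 2 || y > H - 2) next
        if (points_in_polygon(poly, x, y)) next
        if (length(per_x) &&
            min((per_x - x)^2 + (per_y - y)^2) < params$min_separation_um^2) next
        per_x <- c(per_x, x); per_y <- c(per_y, y)
      }
      n <- n_int + n_per
      zone <- c(ifelse(zone_d <= params$cell_diameter_um, "layer1", "deep"),
                rep("periphery", n_per))
      dist_edge <- c(zone_d, rep(0, n_per))
      cells[[ci]] <- data.frame(
        id = id0 + seq_len(n),
        colony = ifelse(zone == "periphery", 0L, ci),
        nearest_colony = ci,
        x_um = c(acc_x, per_x), y_um = c(acc_y, per_y),
        diameter_um = d_draw(n),
        aspect = stats::runif(n, 0.65, 0.95),
        theta = stats::runif(n, 0, pi),
        zone = zone, dist_edge_um = dist_edge,
        stringsAsFactors = FALSE)
      id0 <- id0 + n
    }
    cells <- do.call(rbind, cells)
    n <- nrow(cells)

    ## -- phases, conditional on spatial zone
    props <- list(deep = params$phase_props,
                  layer1 = params$layer1_phase_props,
                  periphery = params$periphery_phase_props)
    phases <- c("G1", "S", "G2", "M")
    cells$phase <- vapply(seq_len(n), function(i)
      sample(phases, 1, prob = props[[cells$zone[i]]]), character(1))

    ## -- channel intensities
    dna_scale <- ifelse(cells$phase %in% c("G2", "M"), 2,
                        ifelse(cells$phase == "S", stats::runif(n, 1.15, 1.85), 1))
    cells$dna_int <- rlnorm_mean(n, 1, params$dna_cv) * params$dna_g1 * dna_scale
    cells$edu_mean <- ifelse(cells$phase == "S",
                             rlnorm_mean(n, params$edu_high, params$edu_cv),
                             rlnorm_mean(n, params$edu_low, params$edu_cv))
    cells$ph3_mean <- ifelse(cells$phase == "M",
                             rlnorm_mean(n, params$ph3_high, params$ph3_cv),
                             rlnorm_mean(n, params$ph3_low, params$ph3_cv))
    p_neg <- ifelse(cells$zone == "periphery", params$marker_neg_frac_periphery,
                    ifelse(cells$phase == "G1", params$marker_neg_frac_g1,
                           params$marker_neg_frac_other))
    cells$marker_negative <- stats::runif(n) < p_neg
    cells$marker_mean <- ifelse(cells$marker_negative,
                                rlnorm_mean(n, params$marker_neg, params$marker_cv),
                                rlnorm_mean(n, params$marker_pos, params$marker_cv))

    structure(list(cells = cells, colonies = colonies,
                   scene_w_um = W, scene_h_um = H,
                   pixel_size = params$pixel_size,
                   params = params, seed = seed),
              class = "SceneTruth")
  })
}

#' @export
print.SceneTruth <- function(x, ...) {
  cat(sprintf("SceneTruth: %d cells in %d colonies, %g x %g um (seed %d)\n",
              nrow(x$cells), length(x$colonies), x$scene_w_um, x$scene_h_um,
              x$seed))
  invisible(x)
}

#' Rasterize colony truth masks
#'
#' @param scene A `SceneTruth`.
#' @return Integer label matrix (rows = y) with colony ids, at the scene's
#'   pixel size.
#' @export
colony_truth_labels <- function(scene) {
  px <- scene$pixel_size
  w <- ceiling(scene$scene_w_um / px); h <- ceiling(scene$scene_h_um / px)
  lab <- matrix(0L, h, w)
  xs <- (seq_len(w) - 0.5) * px; ys <- (seq_len(h) - 0.5) * px
  for (ci in seq_along(scene$colonies)) {
    poly <- scene$colonies[[ci]]
    ix <- which(xs >= min(poly$x) - px & xs <= max(poly$x) + px)
    iy <- which(ys >= min(poly$y) - px & ys <= max(poly$y) + px)
    g <- expand.grid(x = xs[ix], y = ys[iy])
    inside <- points_in_polygon(poly, g$x, g$y)
    lab[cbind(rep(iy, each = length(ix))[inside], rep(ix, length(iy))[inside])] <- ci
  }
  lab
}

## Paint one anisotropic Gaussian nucleus (clipped at 2 sigma) onto a canvas.
## Returns the modified canvas. amp = per-pixel amplitude at the centre.
paint_nucleus <- function(canvas, x_px, y_px, sig_a, sig_b, theta, amp) {
  h <- nrow(canvas); w <- ncol(canvas)
  r <- ceiling(2 * sig_a) + 1
  ix <- max(1, floor(x_px - r + 1)):min(w, ceiling(x_px + r + 1))
  iy <- max(1, floor(y_px - r + 1)):min(h, ceiling(y_px + r + 1))
  if (!length(ix) || !length(iy)) return(canvas)
  xs <- ix - 0.5 - x_px; ys <- iy - 0.5 - y_px
  X <- matrix(xs, length(iy), length(ix), byrow = TRUE)
  Y <- matrix(ys, length(iy), length(ix))
  u <- X * cos(theta) + Y * sin(theta)
  v <- -X * sin(theta) + Y * cos(theta)
  q <- (u / sig_a)^2 + (v / sig_b)^2
  add <- amp * exp(-q / 2) * (q <= 4)
  canvas[iy, ix] <- canvas[iy, ix] + add
  canvas
}

## Pixel footprint of a nucleus: the clipped-ellipse support (q <= 4).
nucleus_footprint_bbox <- function(cell, px) {
  sig_a <- cell$diameter_um / 4 / px
  c(r = 2 * sig_a)
}

#' Render the whole scene into channel images
#'
#' Nuclei are drawn as anisotropic 2-D Gaussians clipped at two sigma (so the
#' footprint diameter equals the cell's stated diameter). The DNA channel is
#' scaled so the pixel sum over a nucleus approximates its true integrated
#' DNA intensity; marker channels are drawn with centre amplitude equal to
#' the cell's true mean intensity. A diffuse within-colony glow
#' (`colony_glow`) is added to the DNA channel.
#'
#' @param scene A `SceneTruth`.
#' @param channels Channels to render, subset of
#'   `c("dna", "edu", "ph3", "marker")`.
#' @return Named list of numeric matrices (rows = y), noise-free.
#' @export
render_scene <- function(scene, channels = c("dna", "edu", "ph3", "marker")) {
  px <- scene$pixel_size
  w <- ceiling(scene$scene_w_um / px); h <- ceiling(scene$scene_h_um / px)
  out <- lapply(channels, function(ch) matrix(0, h, w))
  names(out) <- channels
  if ("dna" %in% channels && scene$params$colony_glow > 0) {
    glow <- (colony_truth_labels(scene) > 0) * scene$params$colony_glow
    out[["dna"]] <- out[["dna"]] + EBImage::gblur(glow, 3)
  }
  cl <- scene$cells
  for (i in seq_len(nrow(cl))) {
    sig_a <- cl$diameter_um[i] / 4 / px
    sig_b <- sig_a * cl$aspect[i]
    xp <- cl$x_um[i] / px; yp <- cl$y_um[i] / px
    for (ch in channels) {
      amp <- switch(ch,
        dna = cl$dna_int[i] / (2 * pi * sig_a * sig_b * px^2),
        edu = cl$edu_mean[i],
        ph3 = cl$ph3_mean[i],
        marker = cl$marker_mean[i])
      out[[ch]] <- paint_nucleus(out[[ch]], xp, yp, sig_a, sig_b,
                                 cl$theta[i], amp)
    }
  }
  out
}

#' Split a scene rendering into a grid of (optionally noisy) field images
#'
#' Crops the noise-free whole-scene rendering into overlapping fields and
#' applies per-field gain and additive background, then (optionally) shot
#' noise and Gaussian read noise. Because all fields are crops of one
#' rendering, the noise-free shared margins of adjacent fields depict
#' identical physical content up to the per-field gain and background.
#'
#' @param scene A `SceneTruth`.
#' @param grid A [grid_spec()]; the region it spans must cover the scene.
#' @param field_effects Optional data frame with columns `fx`, `fy`, `gain`,
#'   `background`; fields not listed get gain 1, background 0.
#' @param channels Channels to render.
#' @param noise If `TRUE`, apply Poisson shot noise and Gaussian read noise.
#' @param read_sd Read-noise standard deviation (a.u.).
#' @param seed Seed for the noise draws (default derives from the scene's).
#' @return List of [field_image()] objects in row-major order (fy slow).
#' @export
render_fields <- function(scene, grid, field_effects = NULL,
                          channels = c("dna", "edu", "ph3", "marker"),
                          noise = FALSE, read_sd = 2, seed = scene$seed + 1000L) {
  stopifnot(inherits(grid, "GridSpec"))
  rd <- region_dim(grid)
  if (rd[1] * grid$pixel_size < scene$scene_w_um - 1e-9 ||
      rd[2] * grid$pixel_size < scene$scene_h_um - 1e-9)
    stop("grid does not cover the scene")
  full <- render_scene(scene, channels)
  ## embed in the (possibly larger) region canvas
  canvas <- lapply(full, function(m) {
    c2 <- matrix(0, rd[2], rd[1])
    c2[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    c2
  })
  fx_gain <- function(fx, fy) {
    if (is.null(field_effects)) return(c(1, 0))
    row <- field_effects[field_effects$fx == fx & field_effects$fy == fy, ]
    if (nrow(row) == 0) return(c(1, 0))
    c(row$gain[1], row$background[1])
  }
  fields <- list()
  with_seed(seed, {
    for (fy in 0:(grid$ny - 1)) for (fx in 0:(grid$nx - 1)) {
      o <- field_origin(grid, fx, fy)
      gb <- fx_gain(fx, fy)
      chs <- lapply(canvas, function(m) {
        crop <- m[o[2] + seq_len(grid$field_h), o[1] + seq_len(grid$field_w)]
        img <- gb[1] * crop + gb[2]
        if (noise) {
          img <- stats::rpois(length(img), pmax(img, 0)) +
            stats::rnorm(length(img), 0, read_sd)
          img <- matrix(img, grid$field_h, grid$field_w)
        }
        img
      })
      fields[[length(fields) + 1]] <- field_image(chs, fx, fy, grid$pixel_size)
    }
  })
  fields
}

#' Rasterize per-field truth label matrices
#'
#' Paints each cell's clipped-ellipse footprint with its truth id into every
#' field whose pixel range it intersects. Used to test consensus relabeling
#' independently of the nuclei segmenter.
#'
#' @param scene A `SceneTruth`.
#' @param grid A [grid_spec()].
#' @return List of integer label matrices in the same order as
#'   [render_fields()], with attribute `fx`/`fy` on each.
#' @export
truth_field_labels <- function(scene, grid) {
  px <- grid$pixel_size
  cl <- scene$cells
  out <- list()
  for (fy in 0:(grid$ny - 1)) for (fx in 0:(grid$nx - 1)) {
    o <- field_origin(grid, fx, fy)
    lab <- matrix(0L, grid$field_h, grid$field_w)
    for (i in seq_len(nrow(cl))) {
      sig_a <- cl$diameter_um[i] / 4 / px
      sig_b <- sig_a * cl$aspect[i]
      xp <- cl$x_um[i] / px - o[1]; yp <- cl$y_um[i] / px - o[2]
      r <- 2 * sig_a
      if (xp < -r - 1 || yp < -r - 1 ||
          xp > grid$field_w + r || yp > grid$field_h + r) next
      ix <- max(1, floor(xp - r)):min(grid$field_w, ceiling(xp + r + 1))
      iy <- max(1, floor(yp - r)):min(grid$field_h, ceiling(yp + r + 1))
      if (!length(ix) || !length(iy) || ix[1] > ix[length(ix)] ||
          iy[1] > iy[length(iy)]) next
      X <- matrix(ix - 0.5 - xp, length(iy), length(ix), byrow = TRUE)
      Y <- matrix(iy - 0.5 - yp, length(iy), length(ix))
      u <- X * cos(cl$theta[i]) + Y * sin(cl$theta[i])
      v <- -X * sin(cl$theta[i]) + Y * cos(cl$theta[i])
      q <- (u / sig_a)^2 + (v / sig_b)^2
      sel <- q <= 4
      sub <- lab[iy, ix, drop = FALSE]
      sub[sel] <- cl$id[i]
      lab[iy, ix] <- sub
    }
    attr(lab, "fx") <- fx; attr(lab, "fy") <- fy
    out[[length(out) + 1]] <- lab
  }
  out
}
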