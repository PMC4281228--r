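## smFISH spot detection in 3-D stacks: morphological top-hat to remove
## out-of-focus light, Laplacian-of-Gaussian sharpening, candidate foci at
## 3-D local maxima, a curvature-times-intensity test statistic, and
## adaptive equalization of per-field thresholds by minimizing the
## margin-spot-count discrepancy between adjacent fields.

## ---- small 3-D helpers ----------------------------------------------------

## Shift a 3-D array by (dy, dx, dz), replicating edges.
shift3d <- function(a, dy, dx, dz) {
  d <- dim(a)
  iy <- pmin(pmax(seq_len(d[1]) + dy, 1), d[1])
  ix <- pmin(pmax(seq_len(d[2]) + dx, 1), d[2])
  iz <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
  a[iy, ix, iz, drop = FALSE]
}

## Separable 3-D Gaussian smoothing with edge replication.
gauss3d <- function(a, sigma) {
  sigma <- rep(sigma, length.out = 3)   # (y, x, z)
  d <- dim(a)
  for (k in 1:3) {
    if (sigma[k] <= 0) next
    r <- max(1L, ceiling(3 * sigma[k]))
    kern <- stats::dnorm(-r:r, 0, sigma[k])
    kern <- kern / sum(kern)
    perm <- c(k, setdiff(1:3, k))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, dp[1], dp[2] * dp[3])
    ## replicate-pad along the filtered dimension
    m <- rbind(m[rep(1, r), , drop = FALSE], m,
               m[rep(dp[1], r), , drop = FALSE])
    f <- stats::filter(m, kern, sides = 2)
    f <- f[(r + 1):(r + dp[1]), , drop = FALSE]
    a <- aperm(array(f, dp), order(perm))
  }
  a
}

## Negated 3-D Laplacian (6-neighbour second differences): point sources
## become positive peaks.
neg_laplacian3d <- function(a) {
  out <- 6 * a
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
    out <- out - shift3d(a, s[1], s[2], s[3])
  out
}

## ---- preprocessing and candidate detection --------------------------------

## Per-plane grayscale top-hat: subtract the morphological opening, removing
## out-of-focus light and plateau backgrounds while keeping point sources.
tophat3d <- function(stack, open_radius) {
  d <- dim(stack)
  brush <- EBImage::makeBrush(2 * open_radius + 1, "disc")
  ## grayscale morphology operates on [0, 1]; rescale around the opening
  lo <- min(stack); hi <- max(stack)
  if (hi <= lo) return(stack - stack)
  bg <- array(0, d)
  for (z in seq_len(d[3]))
    bg[, , z] <- EBImage::opening((stack[, , z] - lo) / (hi - lo),
                                  brush) * (hi - lo) + lo
  stack - bg
}

#' Preprocess an smFISH z-stack
#'
#' Removes slowly varying out-of-focus light by subtracting a per-plane
#' grayscale morphological opening (a top-hat: the opening with a disc
#' larger than a spot erases the spots, so the difference retains them),
#' then applies a Laplacian-of-Gaussian filter, signed so that
#' diffraction-limited spots become positive peaks.
#'
#' @param stack Numeric array `[y, x, z]` with at least 3 planes.
#' @param open_radius Radius (px) of the opening disc; it must exceed the
#'   spot radius or the top-hat will erase the spots (a warning is issued
#'   when `open_radius <= 2 * log_sigma`).
#' @param log_sigma Lateral sigma (px) of the Gaussian in the LoG.
#' @param z_sigma Axial sigma; defaults to `log_sigma * z_aspect`.
#' @param z_aspect Ratio of z-step to pixel size (for anisotropic stacks).
#' @return Filtered array, same shape as `stack`.
#' @export
preprocess_stack <- function(stack, open_radius = 4, log_sigma = 1.3,
                             z_sigma = NULL, z_aspect = 1) {
  d <- dim(stack)
  if (length(d) != 3 || d[3] < 3) stop("stack must have at least 3 z planes")
  if (open_radius <= 2 * log_sigma)
    warning("open_radius <= 2 * log_sigma: the top-hat may erase spots")
  if (is.null(z_sigma)) z_sigma <- log_sigma * z_aspect
  sm <- gauss3d(tophat3d(stack, open_radius),
                c(log_sigma, log_sigma, z_sigma))
  neg_laplacian3d(sm)
}

## 3-D local maxima with 26-connectivity (strictly greater than all
## neighbours), as a logical array.
local_maxima3d <- function(a) {
  ok <- array(TRUE, dim(a))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    sh <- shift3d(a, dy, dx, dz)
    ## replicated edges compare a voxel to itself; treat as satisfied there
    same <- abs(sh - a) < .Machine$double.eps * pmax(abs(a), 1)
    edge_self <- array(FALSE, dim(a))
    if (dy == 1) edge_self[dim(a)[1], , ] <- TRUE
    if (dy == -1) edge_self[1, , ] <- TRUE
    if (dx == 1) edge_self[, dim(a)[2], ] <- TRUE
    if (dx == -1) edge_self[, 1, ] <- TRUE
    if (dz == 1) edge_self[, , dim(a)[3]] <- TRUE
    if (dz == -1) edge_self[, , 1] <- TRUE
    ok <- ok & (a > sh | (edge_self & same))
  }
  ok
}

## 3x3 spatial Hessian of `sm` at voxel (iy, ix, iz) (1-based), by central
## second differences; clamped one voxel inside the stack.
hessian3_at <- function(sm, iy, ix, iz) {
  d <- dim(sm)
  iy <- min(max(iy, 2), d[1] - 1)
  ix <- min(max(ix, 2), d[2] - 1)
  iz <- min(max(iz, 2), d[3] - 1)
  v <- function(dy, dx, dz) sm[iy + dy, ix + dx, iz + dz]
  c0 <- v(0, 0, 0)
  H <- matrix(0, 3, 3)
  H[1, 1] <- v(-1, 0, 0) - 2 * c0 + v(1, 0, 0)         # d2/dy2
  H[2, 2] <- v(0, -1, 0) - 2 * c0 + v(0, 1, 0)         # d2/dx2
  H[3, 3] <- v(0, 0, -1) - 2 * c0 + v(0, 0, 1)         # d2/dz2
  H[1, 2] <- H[2, 1] <- (v(1, 1, 0) - v(1, -1, 0) - v(-1, 1, 0) + v(-1, -1, 0)) / 4
  H[1, 3] <- H[3, 1] <- (v(1, 0, 1) - v(1, 0, -1) - v(-1, 0, 1) + v(-1, 0, -1)) / 4
  H[2, 3] <- H[3, 2] <- (v(0, 1, 1) - v(0, 1, -1) - v(0, -1, 1) + v(0, -1, -1)) / 4
  H
}

## Peak intensity above local background: smoothed value at the peak minus
## the median over the border shell of a box of half-width `r`.
peak_intensity_at <- function(sm, iy, ix, iz, r = 4) {
  d <- dim(sm)
  ys <- max(1, iy - r):min(d[1], iy + r)
  xs <- max(1, ix - r):min(d[2], ix + r)
  zs <- max(1, iz - r):min(d[3], iz + r)
  box <- sm[ys, xs, zs, drop = FALSE]
  inner <- sm[max(1, iy - r + 1):min(d[1], iy + r - 1),
              max(1, ix - r + 1):min(d[2], ix + r - 1),
              max(1, iz - r + 1):min(d[3], iz + r - 1), drop = FALSE]
  shell_sum <- sum(box) - sum(inner)
  shell_n <- length(box) - length(inner)
  bg <- if (shell_n > 0) shell_sum / shell_n else 0
  max(sm[iy, ix, iz] - bg, 0)
}

#' Spot test statistic at a candidate maximum
#'
#' The statistic combines how much the focus resembles a point source with
#' how bright it is: the geometric mean magnitude of the (rectified)
#' negative principal curvatures of the smoothed background-subtracted
#' stack at the peak (a true point source curves downward along all three
#' principal axes, while ridge- or edge-like artifacts have a near-zero
#' curvature and score near zero), multiplied by the peak's
#' Laplacian-of-Gaussian response, i.e. its intensity above the local
#' background after band-pass filtering. It is increasing in every
#' curvature magnitude and in the peak intensity, and scales quadratically
#' when the raw stack is multiplied by a constant.
#'
#' @param raw Raw stack `[y, x, z]`.
#' @param filtered Output of [preprocess_stack()] on `raw`.
#' @param position Integer `c(y, x, z)` 0-based voxel position; must be a
#'   26-connectivity local maximum of `filtered`.
#' @param smooth_sigma Sigma of the Gaussian smoothing applied before
#'   taking curvature.
#' @param open_radius Radius of the opening used to remove the plateau
#'   background before measuring curvature and intensity (match
#'   [preprocess_stack()]).
#' @return Scalar statistic (a.u.).
#' @export
spot_statistic <- function(raw, filtered, position, smooth_sigma = 1,
                           open_radius = 4) {
  iy <- position[1] + 1; ix <- position[2] + 1; iz <- position[3] + 1
  lm <- local_maxima3d(filtered)
  if (!lm[iy, ix, iz]) stop("position is not a local maximum of the filtered stack")
  sm <- gauss3d(tophat3d(raw, open_radius), smooth_sigma)
  spot_statistic_impl(sm, iy, ix, iz, filtered[iy, ix, iz])
}

spot_statistic_impl <- function(sm, iy, ix, iz, fval) {
  H <- hessian3_at(sm, iy, ix, iz)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  ## a point source curves downward along all three axes; ridges and edges
  ## (one curvature near zero) are suppressed by the geometric mean of the
  ## rectified negative curvatures
  curv <- prod(pmax(-ev, 0))^(1 / 3)
  curv * max(fval, 0)
}

#' Detect candidate smFISH foci
#'
#' Candidates are the 26-connectivity local maxima of the filtered stack
#' above a permissive floor, each scored with the curvature-intensity
#' statistic of [spot_statistic()].
#'
#' @param filtered Output of [preprocess_stack()].
#' @param raw The raw stack.
#' @param floor Permissive floor on the filtered value; default the 99th
#'   percentile of the positive filtered values (`NULL`), or supply a
#'   number (0 keeps every positive maximum).
#' @param smooth_sigma Smoothing sigma for the curvature computation.
#' @param open_radius Opening radius used to remove the plateau background
#'   (match [preprocess_stack()]).
#' @return Data frame of class `SpotCandidates`: 0-based `y_px`, `x_px`,
#'   `z_px`, `filtered_value`, `intensity` (peak above local background of
#'   the smoothed background-subtracted stack), `statistic`.
#' @export
detect_candidates <- function(filtered, raw, floor = NULL, smooth_sigma = 1,
                              open_radius = 4) {
  stopifnot(all(dim(filtered) == dim(raw)))
  if (is.null(floor)) {
    pos <- filtered[filtered > 0]
    floor <- if (length(pos)) stats::quantile(pos, 0.99) else Inf
  }
  lm <- local_maxima3d(filtered) & filtered > floor
  ## the outer 1-voxel shell is dominated by boundary artifacts of the
  ## filters; real spots there cannot be localized anyway
  d0 <- dim(filtered)
  lm[c(1, d0[1]), , ] <- FALSE
  lm[, c(1, d0[2]), ] <- FALSE
  lm[, , c(1, d0[3])] <- FALSE
  idx <- which(lm)
  if (!length(idx))
    return(data.frame(y_px = integer(0), x_px = integer(0), z_px = integer(0),
                      filtered_value = numeric(0), intensity = numeric(0),
                      statistic = numeric(0)))
  d <- dim(filtered)
  iy <- (idx - 1) %% d[1] + 1
  ix <- ((idx - 1) %/% d[1]) %% d[2] + 1
  iz <- (idx - 1) %/% (d[1] * d[2]) + 1
  sm <- gauss3d(tophat3d(raw, open_radius), smooth_sigma)
  stat <- numeric(length(idx)); inten <- numeric(length(idx))
  for (i in seq_along(idx)) {
    stat[i] <- spot_statistic_impl(sm, iy[i], ix[i], iz[i], filtered[idx[i]])
    inten[i] <- peak_intensity_at(sm, iy[i], ix[i], iz[i])
  }
  out <- data.frame(y_px = iy - 1L, x_px = ix - 1L, z_px = iz - 1L,
                    filtered_value = filtered[idx], intensity = inten,
                    statistic = stat)
  out[order(-out$statistic), , drop = FALSE]
}

## ---- margin counts and threshold equalization -----------------------------

#' Spot counts in the four shared margins of a field
#'
#' The margins are the physically shared strips defined by the grid overlap:
#' top is `y < overlap`, bottom `y >= field_h - overlap`, and analogously
#' left/right, in 0-based field-local pixels.
#'
#' @param candidates Candidate table for one field (needs `y_px`, `x_px`,
#'   `statistic`).
#' @param grid A [grid_spec()]; its `overlap` must be positive.
#' @param s Threshold: a candidate counts if `statistic >= s`.
#' @return Named numeric vector `c(t=, b=, l=, r=)`.
#' @export
margin_counts <- function(candidates, grid, s) {
  if (grid$overlap <= 0) stop("margins undefined: the grid has zero overlap")
  keep <- candidates$statistic >= s
  y <- candidates$y_px[keep]; x <- candidates$x_px[keep]
  c(t = sum(y < grid$overlap),
    b = sum(y >= grid$field_h - grid$overlap),
    l = sum(x < grid$overlap),
    r = sum(x >= grid$field_w - grid$overlap))
}

## Sorted margin-statistic vectors for one field.
margin_stats <- function(candidates, grid) {
  list(t = sort(candidates$statistic[candidates$y_px < grid$overlap]),
       b = sort(candidates$statistic[candidates$y_px >=
                                       grid$field_h - grid$overlap]),
       l = sort(candidates$statistic[candidates$x_px < grid$overlap]),
       r = sort(candidates$statistic[candidates$x_px >=
                                       grid$field_w - grid$overlap]))
}

count_ge <- function(sorted, s)
  length(sorted) - findInterval(s, sorted, left.open = TRUE)

#' Equalize spot-detection thresholds across a field grid
#'
#' Minimizes the margin-count error function
#' `E(S) = sum over adjacent pairs |f_r(x,y) - f_l(x+1,y)|^p +
#' |f_b(x,y) - f_t(x,y+1)|^p` over the threshold matrix `S = [s_xy]`, where
#' the `f` are the numbers of candidates above threshold in the overlapping
#' margins. Because every `f` is a step function of its threshold, only the
#' candidate statistic values matter; cyclic coordinate descent over each
#' field's sorted unique margin statistics (plus the initial `S0` and
#' infinity) finds an exact per-coordinate minimum, stopping when a full
#' sweep yields no improvement (at most `max_sweeps` sweeps). The result is
#' deterministic and never worse than the constant initial estimate.
#'
#' @param candidates_by_field List of candidate tables, one per field, with
#'   attributes `fx`/`fy`, or a list of `list(candidates=, fx=, fy=)`.
#' @param grid A [grid_spec()]; at least 2 fields.
#' @param norm 2 for squared differences, 1 for absolute (more robust).
#' @param S0 Initial constant threshold; default: Otsu on the pooled log
#'   statistics of all candidates.
#' @param max_sweeps Sweep limit for the coordinate descent.
#' @return Object of class `ThresholdMatrix`: `S` (matrix `[ny, nx]`, entry
#'   `[fy+1, fx+1]` is the field's threshold), `S0`, objective values `E0`
#'   and `E`, the `norm`, and an `objective(Smat)` function.
#' @export
equalize_thresholds <- function(candidates_by_field, grid, norm = 2,
                                S0 = NULL, max_sweeps = 50) {
  stopifnot(inherits(grid, "GridSpec"), norm %in% c(1, 2))
  if (grid$nx * grid$ny < 2) stop("need at least a 1x2 grid to equalize")
  get_cand <- function(cf) {
    if (is.data.frame(cf))
      list(c = cf, fx = attr(cf, "fx"), fy = attr(cf, "fy"))
    else list(c = cf$candidates, fx = cf$fx, fy = cf$fy)
  }
  ms <- vector("list", grid$nx * grid$ny)    # margin stats, index fy*nx+fx+1
  all_stats <- numeric(0)
  for (cf in candidates_by_field) {
    g <- get_cand(cf)
    if (is.null(g$fx) || is.null(g$fy)) stop("candidates need fx/fy")
    ms[[g$fy * grid$nx + g$fx + 1]] <- margin_stats(g$c, grid)
    all_stats <- c(all_stats, g$c$statistic)
  }
  if (any(vapply(ms, is.null, logical(1)))) stop("missing field candidates")
  if (!length(all_stats)) stop("no candidates in any field")
  if (is.null(S0)) {
    ls <- log(all_stats[all_stats > 0])
    S0 <- if (length(unique(ls)) < 2) min(all_stats) else
      exp(otsu_threshold(ls))
  }
  nx <- grid$nx; ny <- grid$ny
  Smat <- matrix(S0, ny, nx)

  pair_terms <- function(Smat) {
    E <- 0
    for (fy in 0:(ny - 1)) for (fx in 0:(nx - 1)) {
      m <- ms[[fy * nx + fx + 1]]
      if (fx < nx - 1) {
        mr <- ms[[fy * nx + fx + 2]]
        E <- E + abs(count_ge(m$r, Smat[fy + 1, fx + 1]) -
                       count_ge(mr$l, Smat[fy + 1, fx + 2]))^norm
      }
      if (fy < ny - 1) {
        mb <- ms[[(fy + 1) * nx + fx + 1]]
        E <- E + abs(count_ge(m$b, Smat[fy + 1, fx + 1]) -
                       count_ge(mb$t, Smat[fy + 2, fx + 1]))^norm
      }
    }
    E
  }

  ## objective restricted to field (fx, fy) as a function of its threshold
  local_E <- function(Smat, fx, fy, s) {
    m <- ms[[fy * nx + fx + 1]]
    E <- 0
    if (fx < nx - 1)
      E <- E + abs(count_ge(m$r, s) -
                     count_ge(ms[[fy * nx + fx + 2]]$l, Smat[fy + 1, fx + 2]))^norm
    if (fx > 0)
      E <- E + abs(count_ge(ms[[fy * nx + fx]]$r, Smat[fy + 1, fx]) -
                     count_ge(m$l, s))^norm
    if (fy < ny - 1)
      E <- E + abs(count_ge(m$b, s) -
                     count_ge(ms[[(fy + 1) * nx + fx + 1]]$t, Smat[fy + 2, fx + 1]))^norm
    if (fy > 0)
      E <- E + abs(count_ge(ms[[(fy - 1) * nx + fx + 1]]$b, Smat[fy, fx + 1]) -
                     count_ge(m$t, s))^norm
    E
  }

  E0 <- pair_terms(Smat)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (fy in 0:(ny - 1)) for (fx in 0:(nx - 1)) {
      m <- ms[[fy * nx + fx + 1]]
      bps <- sort(unique(c(S0, unlist(m), Inf)))
      cur <- Smat[fy + 1, fx + 1]
      Ecur <- local_E(Smat, fx, fy, cur)
      Es <- vapply(bps, function(s) local_E(Smat, fx, fy, s), numeric(1))
      best <- min(Es)
      if (best < Ecur - 1e-12) {
        Smat[fy + 1, fx + 1] <- bps[which(Es <= best + 1e-12)[1]]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  structure(list(S = Smat, S0 = S0, E0 = E0, E = pair_terms(Smat),
                 norm = norm, objective = pair_terms),
            class = "ThresholdMatrix")
}

#' @export
print.ThresholdMatrix <- function(x, ...) {
  cat(sprintf("ThresholdMatrix %dx%d: S0 = %.4g, E0 = %.4g -> E = %.4g (%d-norm)\n",
              ncol(x$S), nrow(x$S), x$S0, x$E0, x$E, x$norm))
  print(signif(x$S, 4))
  invisible(x)
}

## ---- colony mask, cell territories, spot assignment -----------------------

#' Colony mask from diffuse RNA background staining
#'
#' Maximum-projects the stack over z, thresholds with Otsu's method, fills
#' holes, and keeps components of at least `min_area_px`.
#'
#' @param stack Array `[y, x, z]`.
#' @param min_area_px Minimum component area in pixels.
#' @return Logical matrix; blank stacks yield an empty mask.
#' @export
colony_mask_from_background <- function(stack, min_area_px = 200) {
  mp <- apply(stack, c(1, 2), max)
  if (stats::var(as.vector(mp)) == 0)
    return(matrix(FALSE, nrow(mp), ncol(mp)))
  thr <- otsu_threshold(as.vector(mp))
  mask <- EBImage::fillHull(mp > thr)
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  keep <- which(tab >= min_area_px)
  matrix(lab %in% keep, nrow(mp), ncol(mp))
}

#' Expand nucleus labels into cell territories
#'
#' Expands the nucleus outlines until they touch: every pixel of the colony
#' mask is assigned to the nucleus whose boundary is nearest (Euclidean
#' distance to the nucleus's pixels), so territory boundaries form along the
#' loci equidistant from two nuclei, or at the colony edge. Equidistant
#' pixels tie-break to the lower label.
#'
#' @param nuclei_labels Integer label matrix.
#' @param mask Logical colony mask, same shape.
#' @return Integer territory label matrix (0 outside the mask).
#' @export
expand_labels <- function(nuclei_labels, mask) {
  stopifnot(all(dim(nuclei_labels) == dim(mask)))
  labs <- sort(unique(nuclei_labels[nuclei_labels > 0]))
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (!length(labs)) return(out)
  best <- matrix(Inf, nrow(mask), ncol(mask))
  for (l in labs) {   # ascending: ties stay with the lower label
    dl <- EBImage::distmap(1 - (nuclei_labels == l))
    closer <- mask & dl < best
    out[closer] <- l
    best[closer] <- dl[closer]
  }
  out
}

#' Assign detected spots to cells
#'
#' Cell territories are the [expand_labels()] expansion of the nucleus
#' outlines within the colony mask; each spot inside the mask is assigned
#' to the territory containing its `(y, x)` position. Spots outside the
#' mask are unassigned (`NA`); spots inside the mask but in a colony with
#' no nuclei raise a warning and stay unassigned.
#'
#' @param spots Data frame with 0-based `y_px`, `x_px` columns.
#' @param nuclei_labels Integer nucleus label matrix (region frame).
#' @param colony_mask Logical matrix, same shape.
#' @return List with `spots` (input plus `cell_id`) and `counts` (data
#'   frame `cell_id`, `n_spots` for every territory label).
#' @export
assign_spots_to_cells <- function(spots, nuclei_labels, colony_mask) {
  terr <- expand_labels(nuclei_labels, colony_mask)
  iy <- pmin(pmax(round(spots$y_px) + 1, 1), nrow(terr))
  ix <- pmin(pmax(round(spots$x_px) + 1, 1), ncol(terr))
  inside <- colony_mask[cbind(iy, ix)]
  cell <- ifelse(inside, terr[cbind(iy, ix)], NA_integer_)
  if (any(inside & cell == 0, na.rm = TRUE)) {
    warning(sum(inside & cell == 0, na.rm = TRUE),
            " spot(s) inside the mask but in a colony with no nuclei")
    cell[inside & cell == 0] <- NA_integer_
  }
  spots$cell_id <- as.integer(cell)
  labs <- sort(unique(terr[terr > 0]))
  counts <- data.frame(cell_id = labs,
                       n_spots = vapply(labs, function(l)
                         sum(cell == l, na.rm = TRUE), numeric(1)))
  list(spots = spots, counts = counts)
}

#' Merge per-field spot lists into one global list
#'
#' Converts each field's above-threshold spots to region coordinates and
#' removes duplicates arising in shared margins: spots within `radius`
#' pixels (3-D) of an already accepted spot are dropped, keeping the instance
#' with the higher statistic (ties: lower field index). Each physical spot
#' therefore appears once globally.
#'
#' @param spots_by_field List of candidate tables with `fx`/`fy` attributes
#'   (or `list(candidates=, fx=, fy=)`), already thresholded.
#' @param grid A [grid_spec()].
#' @param radius Merge radius in region pixels.
#' @return Data frame with region 0-based `x_px`, `y_px`, `z_px`,
#'   `statistic`, `intensity`, `fx`, `fy`, `global_id`.
#' @export
match_spots_across_fields <- function(spots_by_field, grid, radius = 2) {
  rows <- list()
  for (cf in spots_by_field) {
    if (is.data.frame(cf)) {
      cand <- cf; fx <- attr(cf, "fx"); fy <- attr(cf, "fy")
    } else { cand <- cf$candidates; fx <- cf$fx; fy <- cf$fy }
    if (!nrow(cand)) next
    o <- field_origin(grid, fx, fy)
    cand$x_px <- cand$x_px + o[1]
    cand$y_px <- cand$y_px + o[2]
    cand$fx <- fx; cand$fy <- fy
    rows[[length(rows) + 1]] <- cand
  }
  if (!length(rows))
    return(data.frame(x_px = numeric(0), y_px = numeric(0), z_px = numeric(0),
                      statistic = numeric(0), intensity = numeric(0),
                      fx = integer(0), fy = integer(0), global_id = integer(0)))
  all <- do.call(rbind, rows)
  all <- all[order(-all$statistic, all$fy * grid$nx + all$fx), , drop = FALSE]
  keep <- logical(nrow(all))
  kx <- numeric(0); ky <- numeric(0); kz <- numeric(0)
  for (i in seq_len(nrow(all))) {
    if (length(kx) &&
        min((kx - all$x_px[i])^2 + (ky - all$y_px[i])^2 +
              (kz - all$z_px[i])^2) <= radius^2) next
    keep[i] <- TRUE
    kx <- c(kx, all$x_px[i]); ky <- c(ky, all$y_px[i])
    kz <- c(kz, all$z_px[i])
  }
  out <- all[keep, , drop = FALSE]
  out$global_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
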