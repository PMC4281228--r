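## Colony and nucleus segmentation plus per-object feature extraction.
## Colonies: Gaussian blur + Otsu on the mosaic. Nuclei: smooth ->
## threshold -> distance-transform watershed to split clumps -> area filter.

## gblur whose kernel never exceeds the image (EBImage requires it).
gblur_safe <- function(x, sigma) {
  r <- 2 * ceiling(3 * sigma) + 1
  rmax <- min(dim(x)[1:2])
  if (rmax %% 2 == 0) rmax <- rmax - 1
  EBImage::gblur(x, sigma, radius = min(r, rmax))
}

otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2) return(NA_real_)
  EBImage::otsu(matrix(x, ncol = 1), range = range(x))
}

#' Segment colonies from a mosaic image
#'
#' Gaussian-blurs the (single-channel) mosaic, thresholds the blurred image
#' with Otsu's method, fills holes, removes components smaller than
#' `min_area`, and labels the connected components.
#'
#' @param mosaic Numeric matrix (rows = y), e.g. the DNA-stain mosaic.
#' @param sigma Blur sigma in pixels.
#' @param min_area Minimum colony area in square micrometres.
#' @param pixel_size Micrometres per pixel.
#' @return Integer label matrix; a blank (zero-variance) image yields zero
#'   colonies without error.
#' @export
segment_colonies <- function(mosaic, sigma = 8, min_area = 2000,
                             pixel_size = 1) {
  if (stats::var(as.vector(mosaic)) == 0)
    return(matrix(0L, nrow(mosaic), ncol(mosaic)))
  sm <- gblur_safe(mosaic, sigma)
  thr <- otsu_threshold(as.vector(sm))
  ## refine to the half-height level between the two classes: the boundary
  ## of a blurred step sits at half-height, so this centres the mask edge
  ## on the true colony edge instead of dilating it outward
  fg <- stats::median(sm[sm > thr]); bg <- stats::median(sm[sm <= thr])
  mask <- sm > (fg + bg) / 2
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  min_px <- min_area / pixel_size^2
  tab <- tabulate(lab[lab > 0])
  drop <- which(tab < min_px)
  if (length(drop)) lab[lab %in% drop] <- 0L
  relabel(lab)
}

## Renumber labels 1..n preserving order of first appearance.
relabel <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (!length(u)) return(matrix(0L, nrow(lab), ncol(lab)))
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0] <- match(lab[lab > 0], u)
  out
}

#' Parameters for nuclei segmentation
#'
#' @param sigma Smoothing sigma (px) before thresholding.
#' @param method `"otsu"` for a global threshold, `"local"` to threshold
#'   against a large-scale local background (blur at `local_sigma`) plus
#'   `local_offset`.
#' @param local_sigma,local_offset Local-threshold parameters.
#' @param min_area_um2,max_area_um2 Area gate; objects outside it are
#'   discarded as poorly segmented.
#' @param watershed_tolerance Minimum distance-map depth separating two
#'   seeds (px); raise to split less aggressively.
#' @param discard_border Discard objects touching the field border. Off by
#'   default: partial border objects are resolved later by consensus
#'   relabeling across fields, and only region-border cells are dropped.
#' @return List of class `nuclei_params`.
#' @export
nuclei_params <- function(sigma = 1, method = c("local", "otsu"),
                          local_sigma = 25, local_offset = 12,
                          min_area_um2 = 20, max_area_um2 = 400,
                          watershed_tolerance = 0.2,
                          discard_border = FALSE) {
  method <- match.arg(method)
  out <- as.list(environment())
  class(out) <- "nuclei_params"
  out
}

#' Segment nuclei in one field
#'
#' Pipeline: Gaussian smooth, threshold (global Otsu or local background),
#' fill holes, split touching nuclei by a watershed on the Euclidean
#' distance transform, then gate on area.
#'
#' @param field A [field_image()] or a numeric matrix.
#' @param channel Channel holding the DNA stain (ignored for a matrix).
#' @param params A [nuclei_params()] list.
#' @param pixel_size Micrometres per pixel (taken from the field if given).
#' @return Integer label matrix with attributes `fx`/`fy` when the input is
#'   a `FieldImage`.
#' @export
segment_nuclei <- function(field, channel = "dna", params = nuclei_params(),
                           pixel_size = NULL) {
  if (inherits(field, "FieldImage")) {
    img <- field$channels[[channel]]
    if (is.null(img)) stop("channel '", channel, "' not present in field")
    if (is.null(pixel_size)) pixel_size <- field$pixel_size
  } else img <- field
  if (is.null(pixel_size)) pixel_size <- 1
  if (stats::var(as.vector(img)) == 0) {
    lab <- matrix(0L, nrow(img), ncol(img))
  } else {
    sm <- gblur_safe(img, params$sigma)
    mask <- if (params$method == "otsu") {
      thr <- otsu_threshold(as.vector(sm))
      sm > thr
    } else {
      bg <- gblur_safe(img, params$local_sigma)
      sm > bg + params$local_offset
    }
    mask <- EBImage::fillHull(mask)
    dm <- EBImage::distmap(mask)
    lab <- EBImage::watershed(dm, tolerance = params$watershed_tolerance)
    lab <- matrix(as.integer(lab), nrow(img), ncol(img))
    ## area gate: poorly segmented objects are discarded
    area_px <- tabulate(lab[lab > 0])
    bad <- which(area_px < params$min_area_um2 / pixel_size^2 |
                   area_px > params$max_area_um2 / pixel_size^2)
    if (length(bad)) lab[lab %in% bad] <- 0L
    if (params$discard_border) {
      b <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
      b <- b[b > 0]
      if (length(b)) lab[lab %in% b] <- 0L
    }
    lab <- relabel(lab)
  }
  if (inherits(field, "FieldImage")) {
    attr(lab, "fx") <- field$fx; attr(lab, "fy") <- field$fy
  }
  lab
}

## Crack-boundary perimeter: number of object/background 4-neighbour edges,
## scaled by pi/4 to remove the ~1.27x taxicab bias on smooth shapes.
perimeter_px <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- lab
  cracks <- integer(max(lab, 1))
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- pad[2:(h + 1) + sh[1], 2:(w + 1) + sh[2]]
    edge <- lab > 0 & nb != lab
    if (any(edge)) {
      t <- tabulate(lab[edge], nbins = max(lab))
      cracks[seq_along(t)] <- cracks[seq_along(t)] + t
    }
  }
  cracks * pi / 4
}

## Eccentricity from second central moments of the pixel set.
moments_shape <- function(x, y) {
  mu20 <- stats::var(x) * (length(x) - 1) / length(x)
  mu02 <- stats::var(y) * (length(y) - 1) / length(y)
  mu11 <- mean(x * y) - mean(x) * mean(y)
  tr <- (mu20 + mu02) / 2
  d <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr + d; l2 <- max(tr - d, 0)
  ecc <- if (l1 <= 0) 0 else sqrt(1 - l2 / l1)
  c(ecc = ecc, major = 4 * sqrt(l1), minor = 4 * sqrt(l2))
}

#' Extract per-cell morphology and intensity features
#'
#' For every labelled object: area and perimeter (micrometres), eccentricity
#' from second moments, equivalent diameter, and per channel the integrated
#' intensity (pixel sum), mean intensity, and a simple texture score (the
#' within-object intensity standard deviation).
#'
#' @param labels Integer label matrix.
#' @param channels Named list of numeric matrices, same shape as `labels`.
#' @param pixel_size Micrometres per pixel.
#' @return Data frame, one row per label: `label`, `area_um2`,
#'   `perimeter_um`, `eccentricity`, `equiv_diameter_um`, centroids, and per
#'   channel `<ch>_int`, `<ch>_mean`, `<ch>_sd`.
#' @export
extract_features <- function(labels, channels, pixel_size = 1) {
  stopifnot(is.list(channels), !is.null(names(channels)))
  for (ch in channels)
    if (!all(dim(ch)[1:2] == dim(labels)))
      stop("channel shape does not match the label matrix")
  pix <- label_pixels(labels)
  if (!length(pix)) {
    base <- data.frame(label = integer(0), area_um2 = numeric(0),
                       perimeter_um = numeric(0), eccentricity = numeric(0),
                       equiv_diameter_um = numeric(0),
                       centroid_x_px = numeric(0), centroid_y_px = numeric(0))
    for (nm in names(channels)) {
      base[[paste0(nm, "_int")]] <- numeric(0)
      base[[paste0(nm, "_mean")]] <- numeric(0)
      base[[paste0(nm, "_sd")]] <- numeric(0)
    }
    return(base)
  }
  per <- perimeter_px(labels)
  h <- nrow(labels)
  rows <- lapply(names(pix), function(l) {
    p <- pix[[l]]
    y <- (p - 1) %% h; x <- (p - 1) %/% h
    sh <- moments_shape(x, y)
    a_px <- length(p)
    row <- data.frame(label = as.integer(l),
                      area_um2 = a_px * pixel_size^2,
                      perimeter_um = per[as.integer(l)] * pixel_size,
                      eccentricity = unname(sh["ecc"]),
                      equiv_diameter_um = 2 * sqrt(a_px / pi) * pixel_size,
                      centroid_x_px = mean(x), centroid_y_px = mean(y))
    for (nm in names(channels)) {
      v <- channels[[nm]][p]
      row[[paste0(nm, "_int")]] <- sum(v)
      row[[paste0(nm, "_mean")]] <- mean(v)
      row[[paste0(nm, "_sd")]] <- if (length(v) > 1) stats::sd(v) else 0
    }
    row
  })
  out <- do.call(rbind, rows)
  out[order(out$label), , drop = FALSE]
}

#' Colony-scale features
#'
#' Area, perimeter, eccentricity, and the maximum edge distance (the maximum
#' over interior pixels of the Euclidean distance to the nearest background
#' pixel) per colony, plus the small/medium/large size class derived from it.
#'
#' @param colony_labels Integer colony label matrix.
#' @param pixel_size Micrometres per pixel.
#' @return Data frame: `colony_id`, `area_um2`, `perimeter_um`,
#'   `eccentricity`, `max_edge_distance_um`, `size_class`.
#' @export
colony_features <- function(colony_labels, pixel_size = 1) {
  pix <- label_pixels(colony_labels)
  if (!length(pix))
    return(data.frame(colony_id = integer(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), eccentricity = numeric(0),
                      max_edge_distance_um = numeric(0),
                      size_class = character(0)))
  dm <- EBImage::distmap(colony_labels > 0)
  per <- perimeter_px(colony_labels)
  h <- nrow(colony_labels)
  rows <- lapply(names(pix), function(l) {
    p <- pix[[l]]
    y <- (p - 1) %% h; x <- (p - 1) %/% h
    sh <- moments_shape(x, y)
    med <- max(dm[p]) * pixel_size
    data.frame(colony_id = as.integer(l),
               area_um2 = length(p) * pixel_size^2,
               perimeter_um = per[as.integer(l)] * pixel_size,
               eccentricity = unname(sh["ecc"]),
               max_edge_distance_um = med,
               size_class = classify_colony_size(med))
  })
  out <- do.call(rbind, rows)
  out[order(out$colony_id), , drop = FALSE]
}
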