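## Shared fixtures: small scenes and matching utilities. Everything is
## generated in code at fixed seeds; nothing is read from disk.

## Greedy one-to-one matching of detected centroids to truth positions.
## Returns recall/precision at the given tolerance (um or px).
match_centroids <- function(det_x, det_y, true_x, true_y, tol) {
  used <- rep(FALSE, length(det_x))
  matched <- 0L
  for (i in seq_along(true_x)) {
    d2 <- (det_x - true_x[i])^2 + (det_y - true_y[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && is.finite(d2[j]) && d2[j] <= tol^2) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  list(matched = matched,
       recall = matched / max(length(true_x), 1),
       precision = matched / max(length(det_x), 1))
}

## Paint an isotropic Gaussian nucleus (clipped at 2 sigma) on a canvas.
paint_disc_nucleus <- function(canvas, x, y, sigma, amp) {
  h <- nrow(canvas); w <- ncol(canvas)
  r <- ceiling(2 * sigma) + 1
  ix <- max(1, floor(x - r)):min(w, ceiling(x + r))
  iy <- max(1, floor(y - r)):min(h, ceiling(y + r))
  X <- matrix(ix - 0.5 - x, length(iy), length(ix), byrow = TRUE)
  Y <- matrix(iy - 0.5 - y, length(iy), length(ix))
  q <- (X^2 + Y^2) / sigma^2
  canvas[iy, ix] <- canvas[iy, ix] + amp * exp(-q / 2) * (q <= 4)
  canvas
}

## Rasterized disc label matrix.
disc_labels <- function(h, w, cx, cy, r, label = 1L) {
  lab <- matrix(0L, h, w)
  X <- matrix(seq_len(w) - 0.5, h, w, byrow = TRUE)
  Y <- matrix(seq_len(h) - 0.5, h, w)
  lab[(X - cx)^2 + (Y - cy)^2 <= r^2] <- label
  lab
}

## Small smFISH benchmark shared by several tests (generated once per run).
fish_bench <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- grid_spec(2, 1, 120, 120, overlap = 24)
      p <- smfish_params(n_cells = 8, spots_per_cell = 30, min_snr = 6)
      sim <- generate_smfish_stack(p, g, seed = 1)
      f1 <- sim$fields[[1]]$channels$fish
      filt <- preprocess_stack(f1)
      cache <<- list(grid = g, params = p, sim = sim, raw = f1, filt = filt)
    }
    cache
  }
})
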