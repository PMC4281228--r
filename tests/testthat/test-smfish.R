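test_that("preprocessing: flat background vanishes, peaks survive gradients", {
  flat <- array(7, c(40, 40, 5))
  out <- preprocess_stack(flat, open_radius = 4, log_sigma = 1.3)
  expect_lt(max(abs(out)), 1e-9)
  expect_error(preprocess_stack(matrix(0, 10, 10)), "z planes")
  expect_warning(preprocess_stack(flat, open_radius = 2, log_sigma = 1.3),
                 "erase")

  ## single PSF on flat background: global maximum within 1 px of truth
  mk <- function(bg) {
    st <- array(0, c(41, 41, 7)) + bg
    for (z in 1:7) for (y in 1:41) {
      st[y, , z] <- st[y, , z] +
        50 * exp(-((seq_len(41) - 0.5 - 20.3)^2 + (y - 0.5 - 21.6)^2) / (2 * 1.3^2)) *
        exp(-(z - 0.5 - 3.5)^2 / (2 * 1.6^2))
    }
    st
  }
  am <- function(st) {
    f <- preprocess_stack(st)
    w <- which(f == max(f), arr.ind = TRUE)[1, ]
    w
  }
  w1 <- am(mk(0))
  expect_lt(abs(w1[1] - 0.5 - 21.6), 1.01)
  expect_lt(abs(w1[2] - 0.5 - 20.3), 1.01)
  ## smooth background gradient does not move the peak
  grad <- outer(seq(0, 30, length.out = 41), rep(1, 41))
  stg <- mk(0)
  for (z in 1:7) stg[, , z] <- stg[, , z] + grad
  expect_equal(am(stg), w1)
})

test_that("candidate detection finds planted spots and separates close pairs", {
  expect_equal(nrow(detect_candidates(array(0, c(20, 20, 5)),
                                      array(0, c(20, 20, 5)), floor = 0)), 0)

  b <- fish_bench()
  sd_neg <- sqrt(mean(b$filt[b$filt < 0]^2))
  cand <- detect_candidates(b$filt, b$raw, floor = 2 * sd_neg)
  tf <- b$sim$spots_by_field[b$sim$spots_by_field$fx == 0, ]
  expect_gte(nrow(cand), nrow(tf))
  ## the top-n candidates by statistic sit on truth positions
  top <- cand[seq_len(nrow(tf)), ]
  hits <- sapply(seq_len(nrow(tf)), function(i)
    min((top$x_px - tf$x_local[i])^2 + (top$y_px - tf$y_local[i])^2 +
          (top$z_px - tf$z_px[i])^2))
  expect_gte(mean(hits <= 4), 0.95)

  ## two spots 10 px apart give two distinct candidates
  st <- array(0, c(40, 40, 7))
  for (z in 1:7) for (y in 1:40) {
    g <- exp(-(z - 4)^2 / (2 * 1.6^2)) * 60
    st[y, , z] <- g * exp(-((seq_len(40) - 15)^2 + (y - 20)^2) / (2 * 1.3^2)) +
      g * exp(-((seq_len(40) - 25)^2 + (y - 20)^2) / (2 * 1.3^2))
  }
  cc <- detect_candidates(preprocess_stack(st), st, floor = 0)
  cc <- cc[cc$statistic > 0.1 * max(cc$statistic), ]
  expect_equal(nrow(cc), 2)
})

test_that("spot statistic: quadratic scaling, sharpness ordering, non-maximum error", {
  mkpsf <- function(amp, sxy) {
    st <- array(0, c(31, 31, 7))
    for (z in 1:7) for (y in 1:31)
      st[y, , z] <- st[y, , z] +
        amp * exp(-((seq_len(31) - 16)^2 + (y - 16)^2) / (2 * sxy^2)) *
        exp(-(z - 4)^2 / (2 * 1.6^2))
    st
  }
  s1 <- mkpsf(50, 1.3); s2 <- mkpsf(100, 1.3)
  f1 <- preprocess_stack(s1); f2 <- preprocess_stack(s2)
  pos <- c(15, 15, 3)   # 0-based centre
  v1 <- spot_statistic(s1, f1, pos)
  v2 <- spot_statistic(s2, f2, pos)
  expect_gt(v1, 0)
  expect_lt(abs(v2 / v1 - 4), 0.4)    # x4 within 10%

  ## a broad blob of equal peak intensity scores strictly lower
  sb <- mkpsf(50, 3.5)
  fb <- preprocess_stack(sb)
  expect_gt(v1, spot_statistic(sb, fb, pos))

  expect_error(spot_statistic(s1, f1, c(2, 2, 3)), "not a local maximum")
})

test_that("statistic separates planted spots from noise almost perfectly", {
  b <- fish_bench()
  sd_neg <- sqrt(mean(b$filt[b$filt < 0]^2))
  cand <- detect_candidates(b$filt, b$raw, floor = 2 * sd_neg)
  tf <- b$sim$spots_by_field[b$sim$spots_by_field$fx == 0, ]
  istrue <- sapply(seq_len(nrow(cand)), function(i)
    any((cand$x_px[i] - tf$x_local)^2 + (cand$y_px[i] - tf$y_local)^2 +
          (cand$z_px[i] - tf$z_px)^2 <= 4))
  r <- rank(cand$statistic)
  auc <- (mean(r[istrue]) - (sum(istrue) + 1) / 2) / sum(!istrue)
  expect_gte(auc, 0.99)
})

test_that("margin counts follow the shared strips and the threshold", {
  g <- grid_spec(2, 2, 100, 100, overlap = 20)
  cand <- data.frame(y_px = c(5, 50, 95, 50, 50), x_px = c(50, 5, 50, 95, 50),
                     statistic = c(10, 20, 30, 40, 50))
  m0 <- margin_counts(cand, g, 0)
  expect_equal(unname(m0), c(1, 1, 1, 1))
  expect_equal(unname(margin_counts(cand, g, Inf)), c(0, 0, 0, 0))
  ## three candidates in the right margin, threshold below all statistics
  c3 <- data.frame(y_px = c(30, 40, 50), x_px = c(85, 90, 99),
                   statistic = c(5, 6, 7))
  expect_equal(margin_counts(c3, g, 1)[["r"]], 3)
  ## monotone non-increasing in s
  for (s in c(15, 25, 35, 45, 55))
    expect_true(all(margin_counts(cand, g, s) <= margin_counts(cand, g, s - 10)))
  g0 <- grid_spec(2, 2, 100, 100, overlap = 0)
  expect_error(margin_counts(cand, g0, 0), "zero overlap")
})

test_that("threshold equalization: symmetry, descent, exhaustive 1x2 oracle", {
  g <- grid_spec(2, 1, 100, 100, overlap = 30)
  ## identical content in the shared margin, equal gain: constant S optimal
  set.seed(31)
  shared <- data.frame(y_px = runif(12, 0, 100), x_px = runif(12, 70, 100),
                       statistic = exp(rnorm(12, 3, 1)))
  cA <- shared
  cB <- shared; cB$x_px <- cB$x_px - 70
  attr(cA, "fx") <- 0; attr(cA, "fy") <- 0
  attr(cB, "fx") <- 1; attr(cB, "fy") <- 0
  tm <- equalize_thresholds(list(cA, cB), g, norm = 2, S0 = 10)
  expect_equal(tm$E, 0)
  expect_lte(tm$E, tm$E0)

  ## field 2 at half gain: statistics scale by 0.25; the minimizer must
  ## match an exhaustive search over all breakpoint pairs
  cB2 <- cB; cB2$statistic <- cB2$statistic * 0.25
  attr(cB2, "fx") <- 1; attr(cB2, "fy") <- 0
  tm2 <- equalize_thresholds(list(cA, cB2), g, norm = 2, S0 = 10)
  expect_lte(tm2$E, tm2$E0)
  expect_lt(tm2$S[1, 2], tm2$S[1, 1])    # lower threshold for the dim field
  bps1 <- c(sort(unique(cA$statistic)), 10, Inf)
  bps2 <- c(sort(unique(cB2$statistic)), 10, Inf)
  fr <- function(s) sum(cA$statistic >= s & cA$x_px >= 70)
  fl <- function(s) sum(cB2$statistic >= s & cB2$x_px < 30)
  best <- Inf
  for (s1 in bps1) for (s2 in bps2)
    best <- min(best, (fr(s1) - fl(s2))^2)
  expect_equal(tm2$E, best)
  ## and the discrepancy at the found thresholds is the brute-force minimum
  expect_equal((fr(tm2$S[1, 1]) - fl(tm2$S[1, 2]))^2, best)

  expect_error(equalize_thresholds(list(), grid_spec(1, 1, 50, 50, 10)),
               "1x2")
})

test_that("equalization reduces margin discrepancy on a gain-gradient region", {
  g <- grid_spec(3, 2, 100, 100, overlap = 20)
  p <- smfish_params(n_cells = 12, spots_per_cell = 30, min_snr = 6,
                     gain_gradient = 0.4)
  sim <- generate_smfish_stack(p, g, seed = 3)
  cands <- lapply(sim$fields, function(f) {
    filt <- preprocess_stack(f$channels$fish)
    sd_neg <- sqrt(mean(filt[filt < 0]^2))
    cc <- detect_candidates(filt, f$channels$fish, floor = 2 * sd_neg)
    attr(cc, "fx") <- f$fx; attr(cc, "fy") <- f$fy
    cc
  })
  for (nrm in c(2, 1)) {
    tm <- equalize_thresholds(cands, g, norm = nrm)
    expect_lt(tm$E, tm$E0)   # strict reduction under a nonzero gradient
  }
})

test_that("colony mask from background staining", {
  b <- fish_bench()
  mask <- colony_mask_from_background(b$raw)
  truth <- b$sim$colony_mask[1:120, 1:120]
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.9)
  expect_equal(sum(colony_mask_from_background(array(3, c(30, 30, 4)))), 0)
  ## point sources barely perturb the mask
  st2 <- b$raw
  st2[60, 60, 5] <- st2[60, 60, 5] + 1000
  mask2 <- colony_mask_from_background(st2)
  expect_lt(mean(mask != mask2), 0.01)
})

test_that("cell territories and spot assignment", {
  mask <- disc_labels(80, 80, 40, 40, 35) > 0
  nuc <- disc_labels(80, 80, 25, 40, 6)
  ## single nucleus: every spot in the colony is assigned to it
  sp <- data.frame(y_px = c(40, 10, 40), x_px = c(55, 70, 41))
  a1 <- assign_spots_to_cells(sp, nuc, mask)
  expect_equal(a1$spots$cell_id, c(1L, NA, 1L))   # spot 2 is outside the mask
  expect_equal(a1$counts$n_spots, 2)

  ## two nuclei: midway spot tie-breaks to the lower label
  nuc2 <- nuc
  nuc2[disc_labels(80, 80, 55, 40, 6) > 0] <- 2L
  terr <- expand_labels(nuc2, mask)
  expect_equal(terr[40, 40], 1L)                  # equidistant midpoint
  expect_true(all(terr[mask] > 0))
  expect_equal(sort(unique(as.vector(terr))), c(0L, 1L, 2L))
  a2 <- assign_spots_to_cells(data.frame(y_px = 40, x_px = 60), nuc2, mask)
  expect_equal(a2$spots$cell_id, 2L)

  ## nuclei-free colony: spots stay unassigned with a warning
  expect_warning(
    a3 <- assign_spots_to_cells(sp[1, ], matrix(0L, 80, 80), mask),
    "no nuclei")
  expect_true(is.na(a3$spots$cell_id))
})

test_that("per-cell counts match truth for interior spots", {
  b <- fish_bench()
  sim <- b$sim
  ## noiseless reassignment of the truth spots themselves: counts must agree
  ## exactly for spots at least 2 px from a territory boundary
  terr <- expand_labels(sim$nuclei_labels, sim$colony_mask)
  asn <- assign_spots_to_cells(
    data.frame(y_px = sim$spots$y_px, x_px = sim$spots$x_px),
    sim$nuclei_labels, sim$colony_mask)
  ok <- !is.na(asn$spots$cell_id)
  expect_gte(mean(asn$spots$cell_id[ok] == sim$spots$cell[ok]), 0.97)
})

test_that("spot matching across fields removes duplicates only", {
  g <- grid_spec(2, 1, 100, 100, overlap = 30)
  ## same physical spot in both fields: region x = 80
  cA <- data.frame(y_px = 50, x_px = 80, z_px = 4, statistic = 9,
                   intensity = 1)
  cB <- data.frame(y_px = 50, x_px = 10, z_px = 4, statistic = 7,
                   intensity = 1)
  attr(cA, "fx") <- 0; attr(cA, "fy") <- 0
  attr(cB, "fx") <- 1; attr(cB, "fy") <- 0
  out <- match_spots_across_fields(list(cA, cB), g, radius = 2)
  expect_equal(nrow(out), 1)
  expect_equal(out$statistic, 9)     # the higher-statistic instance is kept

  ## distinct spots farther apart than the radius stay distinct
  cB2 <- data.frame(y_px = 55, x_px = 10, z_px = 4, statistic = 7,
                    intensity = 1)
  attr(cB2, "fx") <- 1; attr(cB2, "fy") <- 0
  out2 <- match_spots_across_fields(list(cA, cB2), g, radius = 2)
  expect_equal(nrow(out2), 2)
})

test_that("global spot recovery across a grid at comfortable SNR", {
  b <- fish_bench()
  g <- b$grid
  cands <- lapply(b$sim$fields, function(f) {
    filt <- preprocess_stack(f$channels$fish)
    sd_neg <- sqrt(mean(filt[filt < 0]^2))
    cc <- detect_candidates(filt, f$channels$fish, floor = 2 * sd_neg)
    attr(cc, "fx") <- f$fx; attr(cc, "fy") <- f$fy
    cc
  })
  tm <- equalize_thresholds(cands, g)
  thresholded <- lapply(cands, function(cc) {
    s <- tm$S[attr(cc, "fy") + 1, attr(cc, "fx") + 1]
    out <- cc[cc$statistic >= s, ]
    attr(out, "fx") <- attr(cc, "fx"); attr(out, "fy") <- attr(cc, "fy")
    out
  })
  glob <- match_spots_across_fields(thresholded, g, radius = 2)
  tr <- b$sim$spots
  d2min <- sapply(seq_len(nrow(tr)), function(i)
    min((glob$x_px - tr$x_px[i])^2 + (glob$y_px - tr$y_px[i])^2 +
          (glob$z_px - tr$z_px[i])^2))
  expect_gte(mean(d2min <= 4), 0.9)
  expect_false(any(duplicated(glob$global_id)))
})
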