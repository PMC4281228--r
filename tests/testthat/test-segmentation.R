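test_that("colony segmentation finds blobs, ignores specks, survives blanks", {
  sc <- generate_colony_scene(scene_params(n_colonies = 2,
                                           cells_per_colony = 80,
                                           scene_w_um = 500, scene_h_um = 500,
                                           colony_radius_um = 90), seed = 4)
  img <- render_scene(sc, "dna")$dna
  lab <- segment_colonies(img)
  truth <- colony_truth_labels(sc)
  expect_equal(max(lab), 2)
  iou <- sum(lab > 0 & truth > 0) / sum(lab > 0 | truth > 0)
  expect_gte(iou, 0.9)

  expect_equal(max(segment_colonies(matrix(5, 50, 50))), 0)

  ## one blob plus a speck below min_area
  img2 <- matrix(0, 200, 200)
  img2 <- paint_disc_nucleus(img2, 70, 70, 25, 100)
  img2 <- paint_disc_nucleus(img2, 170, 170, 4, 100)
  lab2 <- segment_colonies(img2, sigma = 3, min_area = 800)
  expect_equal(max(lab2), 1)
})

test_that("nuclei segmentation: isolated nuclei, clump splitting, empty field", {
  ## 20 well separated nuclei on a flat background
  set.seed(21)
  img <- matrix(0, 220, 220)
  gx <- rep(seq(25, 195, length.out = 5), 4)
  gy <- rep(seq(25, 190, length.out = 4), each = 5)
  gx <- gx + runif(20, -4, 4); gy <- gy + runif(20, -4, 4)
  for (i in 1:20) img <- paint_disc_nucleus(img, gx[i], gy[i], 3, 120)
  lab <- segment_nuclei(img)
  cen <- label_centroids(lab)
  expect_equal(nrow(cen), 20)
  m <- match_centroids(cen$x_px + 0.5, cen$y_px + 0.5, gx, gy, tol = 1)
  expect_equal(m$matched, 20)

  ## two nuclei overlapping by ~20% of their diameter split into two
  img2 <- matrix(0, 80, 80)
  img2 <- paint_disc_nucleus(img2, 34, 40, 3, 120)   # diameter 12 px
  img2 <- paint_disc_nucleus(img2, 43.6, 40, 3, 120) # centres 0.8 d apart
  lab2 <- segment_nuclei(img2)
  expect_equal(max(lab2), 2)

  expect_equal(max(segment_nuclei(matrix(0, 60, 60))), 0)
})

test_that("nuclei recall and precision reach 0.95 on rendered fields", {
  sc <- generate_colony_scene(scene_params(), seed = 2)
  g <- grid_spec(2, 2, 330, 330, overlap = 60)
  flds <- render_fields(sc, g, noise = TRUE, channels = "dna")
  labs <- lapply(flds, segment_nuclei, channel = "dna")
  cons <- consensus_segmentation(labs, g, 15)
  cl <- sc$cells
  r <- cl$diameter_um / 2
  interior <- cl$x_um - r > 1 & cl$y_um - r > 1
  m <- match_centroids(cons$mapping$centroid_x_um, cons$mapping$centroid_y_um,
                       cl$x_um[interior], cl$y_um[interior], tol = 3)
  expect_gte(m$recall, 0.95)
  expect_gte(m$matched / nrow(cons$mapping), 0.95)
})

test_that("cell features match closed forms on simple shapes", {
  ## uniform disc: area, mean, integrated, eccentricity, perimeter
  lab <- disc_labels(60, 60, 30, 30, 10)
  ch <- list(stain = (lab > 0) * 5)
  f <- extract_features(lab, ch, pixel_size = 1)
  expect_equal(f$area_um2, pi * 100, tolerance = 0.02)
  expect_equal(f$stain_mean, 5)
  expect_equal(f$stain_int, 5 * f$area_um2, tolerance = 1e-12)
  expect_lt(f$eccentricity, 0.1)
  expect_equal(f$perimeter_um, 2 * pi * 10, tolerance = 0.06)
  expect_equal(f$stain_sd, 0)

  ## intensity linearity: scaling a channel scales intensity features only
  f2 <- extract_features(lab, list(stain = ch$stain * 2), pixel_size = 1)
  expect_equal(f2$stain_int, 2 * f$stain_int)
  expect_equal(f2$stain_mean, 2 * f$stain_mean)
  expect_equal(f2$area_um2, f$area_um2)
  expect_equal(f2$eccentricity, f$eccentricity)

  ## 2:1 axis ratio ellipse: eccentricity sqrt(1 - 1/4)
  lab3 <- matrix(0L, 80, 80)
  X <- matrix(seq_len(80) - 0.5, 80, 80, byrow = TRUE)
  Y <- matrix(seq_len(80) - 0.5, 80, 80)
  lab3[((X - 40) / 24)^2 + ((Y - 40) / 12)^2 <= 1] <- 1L
  f3 <- extract_features(lab3, list(stain = (lab3 > 0) * 1), 1)
  expect_equal(f3$eccentricity, sqrt(1 - 1 / 4), tolerance = 0.01)

  ## micrometre scaling: doubling pixel size quadruples area, doubles lengths
  f4 <- extract_features(lab, ch, pixel_size = 2)
  expect_equal(f4$area_um2, 4 * f$area_um2)
  expect_equal(f4$perimeter_um, 2 * f$perimeter_um)
  expect_error(extract_features(lab, list(stain = matrix(0, 10, 10))),
               "shape")
})

test_that("colony features: max edge distance on disc and annulus", {
  lab <- disc_labels(140, 140, 70, 70, 50)
  cf <- colony_features(lab, pixel_size = 1)
  expect_equal(cf$max_edge_distance_um, 50, tolerance = 0.04)
  expect_equal(cf$size_class, "small")

  ## annulus: max edge distance is half the ring width
  ann <- disc_labels(140, 140, 70, 70, 50)
  ann[disc_labels(140, 140, 70, 70, 30) > 0] <- 0L
  cfa <- colony_features(ann, 1)
  expect_equal(cfa$max_edge_distance_um, 10, tolerance = 0.08)
  ## never more than half the smaller bounding-box side
  expect_lte(cfa$max_edge_distance_um, 50)

  two <- lab
  two[disc_labels(140, 140, 15, 15, 8) > 0] <- 2L
  cf2 <- colony_features(two, 1)
  expect_equal(cf2$colony_id, c(1L, 2L))
})

test_that("window-summed DNA intensity is proportional to cell count", {
  sc <- generate_colony_scene(scene_params(), seed = 6)
  img <- render_scene(sc, "dna")$dna
  ## 100 um windows over the scene; compare integrated DNA to truth count
  w <- 100
  sums <- counts <- c()
  for (wx in 0:5) for (wy in 0:5) {
    xs <- wx * w + seq_len(w); ys <- wy * w + seq_len(w)
    sums <- c(sums, sum(img[ys, xs]))
    counts <- c(counts, sum(sc$cells$x_um >= wx * w & sc$cells$x_um < (wx + 1) * w &
                              sc$cells$y_um >= wy * w & sc$cells$y_um < (wy + 1) * w))
  }
  keep <- counts > 0
  expect_gt(cor(sums[keep], counts[keep]), 0.9)
})
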