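test_that("mosaicking: identity, exact concatenation, missing fields", {
  g1 <- grid_spec(1, 1, 50, 50, overlap = 0)
  f <- field_image(list(dna = matrix(runif(2500), 50, 50)), 0, 0)
  expect_equal(mosaic_fields(list(f), g1, "dna"), f$channels$dna)

  g2 <- grid_spec(2, 1, 50, 50, overlap = 0)
  fa <- field_image(list(dna = matrix(runif(2500), 50, 50)), 0, 0)
  fb <- field_image(list(dna = matrix(runif(2500), 50, 50)), 1, 0)
  expect_equal(mosaic_fields(list(fa, fb), g2, "dna"),
               cbind(fa$channels$dna, fb$channels$dna))
  expect_error(mosaic_fields(list(fa), g2, "dna"), "missing field")
})

test_that("mosaic of an overlapping synthetic grid matches the direct rendering", {
  p <- scene_params(n_colonies = 2, cells_per_colony = 50,
                    scene_w_um = 400, scene_h_um = 400, colony_radius_um = 80)
  sc <- generate_colony_scene(p, seed = 2)
  g <- grid_spec(2, 2, 230, 230, overlap = 60)
  flds <- render_fields(sc, g, channels = "dna", noise = FALSE)
  mosaic <- mosaic_fields(flds, g, "dna")
  direct <- render_scene(sc, "dna")$dna
  expect_equal(mosaic[1:400, 1:400], direct, tolerance = 1e-12)
})

test_that("consensus keeps the larger of two corresponding instances", {
  g <- grid_spec(2, 1, 60, 60, overlap = 30)
  ## the same object seen by both fields at the same region position:
  ## region x in [32, 55): field0 local x 32..54, field1 local x 2..24
  lab0 <- matrix(0L, 60, 60)
  lab0[20:39, 33:55] <- 1L          # 20 x 23 = 460 px
  lab1 <- matrix(0L, 60, 60)
  lab1[21:38, 4:25] <- 1L           # 18 x 22 = 396 px, overlapping footprint
  attr(lab0, "fx") <- 0; attr(lab0, "fy") <- 0
  attr(lab1, "fx") <- 1; attr(lab1, "fy") <- 0
  cons <- consensus_segmentation(list(lab0, lab1), g, max_cell_diameter = 25)
  expect_equal(nrow(cons$mapping), 1)
  expect_equal(cons$mapping$field_x, 0)        # larger instance won
  expect_equal(cons$mapping$area_px, 460)
  expect_equal(sum(cons$labels > 0), 460)

  ## swap sizes: now field 1 has the larger instance
  lab0b <- matrix(0L, 60, 60); lab0b[21:38, 34:54] <- 1L   # 18 x 21
  lab1b <- matrix(0L, 60, 60); lab1b[20:39, 3:25] <- 1L    # 20 x 23
  attr(lab0b, "fx") <- 0; attr(lab0b, "fy") <- 0
  attr(lab1b, "fx") <- 1; attr(lab1b, "fy") <- 0
  cons2 <- consensus_segmentation(list(lab0b, lab1b), g, 25)
  expect_equal(cons2$mapping$field_x, 1)
})

test_that("overlapping but distant objects are kept distinct", {
  g <- grid_spec(2, 1, 60, 60, overlap = 30)
  ## two long thin objects that share a pixel in region space but whose
  ## centroids are far apart (touching neighbours, not duplicates)
  lab0 <- matrix(0L, 60, 60); lab0[10, 31:58] <- 1L
  lab1 <- matrix(0L, 60, 60); lab1[10:40, 28] <- 1L
  attr(lab0, "fx") <- 0; attr(lab0, "fy") <- 0
  attr(lab1, "fx") <- 1; attr(lab1, "fy") <- 0
  cons <- consensus_segmentation(list(lab0, lab1), g, max_cell_diameter = 8)
  expect_equal(nrow(cons$mapping), 2)
})

test_that("single-field consensus equals its labels minus border objects", {
  g <- grid_spec(1, 1, 80, 80, overlap = 0)
  lab <- disc_labels(80, 80, 40, 40, 10)
  lab[disc_labels(80, 80, 3, 40, 6) > 0] <- 2L    # touches the border
  attr(lab, "fx") <- 0; attr(lab, "fy") <- 0
  cons <- suppressWarnings(consensus_segmentation(list(lab), g, 20))
  expect_equal(nrow(cons$mapping), 1)
  expect_equal(sort(unique(as.vector(cons$labels))), c(0, 1))
  expect_equal(sum(cons$labels > 0), sum(lab == 1))
})

test_that("consensus on a truth-labelled 3x3 grid is duplicate-free and lossless", {
  p <- scene_params(n_colonies = 2, cells_per_colony = 70,
                    scene_w_um = 420, scene_h_um = 420, colony_radius_um = 80)
  sc <- generate_colony_scene(p, seed = 9)
  g <- grid_spec(3, 3, 160, 160, overlap = 30)   # overlap = 2 x max diameter
  tl <- truth_field_labels(sc, g)
  cons <- consensus_segmentation(tl, g, max_cell_diameter = 15)
  cl <- sc$cells
  r <- cl$diameter_um / 2
  interior <- cl$x_um - r > 1 & cl$y_um - r > 1 &
    cl$x_um + r < region_dim(g)[1] - 1 & cl$y_um + r < region_dim(g)[2] - 1
  m <- match_centroids(cons$mapping$centroid_x_um, cons$mapping$centroid_y_um,
                       cl$x_um[interior], cl$y_um[interior], tol = 2)
  expect_equal(m$matched, sum(interior))          # no losses
  expect_equal(nrow(cons$mapping), sum(interior)) # no duplicates
})

test_that("addresses carry colony ids, with 0 for peripheral centroids", {
  colonies <- disc_labels(100, 100, 30, 50, 20, 3L)
  cells <- disc_labels(100, 100, 30, 50, 5, 1L)           # inside colony 3
  cells[disc_labels(100, 100, 80, 50, 5) > 0] <- 2L       # in background
  addr <- assign_addresses(cells, colonies, pixel_size = 0.5)
  addr <- addr[order(addr$global_label), ]
  expect_equal(addr$colony_id, c(3L, 0L))
  expect_equal(addr$nearest_colony_id, c(3L, 3L))
  expect_false(any(duplicated(addr$global_label)))
  expect_equal(addr$centroid_x_um, addr$centroid_x_px * 0.5)
  expect_error(assign_addresses(cells, colonies[1:50, ]), "same shape")
})
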