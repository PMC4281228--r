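test_that("scene generation is deterministic and respects its own geometry", {
  p <- scene_params(n_colonies = 3, cells_per_colony = 100)
  s1 <- generate_colony_scene(p, seed = 1)
  s2 <- generate_colony_scene(p, seed = 1)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$colonies, s2$colonies)
  expect_equal(nrow(s1$cells), round(3 * 100 * (1 + p$frac_peripheral)))
  expect_false(any(duplicated(s1$cells$id)))
  ## every non-peripheral cell centroid lies inside its colony polygon;
  ## peripheral cells lie outside
  for (ci in 1:3) {
    poly <- s1$colonies[[ci]]
    inside <- s1$cells$colony == ci
    expect_true(all(mgcv::in.out(as.matrix(poly),
                                 cbind(s1$cells$x_um[inside],
                                       s1$cells$y_um[inside]))))
  }
  per <- s1$cells$zone == "periphery"
  expect_true(all(s1$cells$colony[per] == 0))
  expect_true(all(s1$cells$dist_edge_um[per] == 0))
  expect_true(all(s1$cells$diameter_um <= p$max_cell_diameter_um))
})

test_that("invalid phase proportions are rejected", {
  expect_error(scene_params(phase_props = c(G1 = .5, S = .3, G2 = .3, M = .1)),
               "summing to 1")
})

test_that("phase mixture matches the multinomial expectation within 3 sigma", {
  props <- c(G1 = 0.40, S = 0.30, G2 = 0.25, M = 0.05)
  p <- scene_params(n_colonies = 2, cells_per_colony = 1000,
                    scene_w_um = 1200, scene_h_um = 1200,
                    colony_radius_um = 220, frac_peripheral = 0,
                    phase_props = props, periphery_phase_props = props,
                    layer1_phase_props = props)
  sc <- generate_colony_scene(p, seed = 42)
  n <- nrow(sc$cells)
  emp <- table(factor(sc$cells$phase, levels = names(props))) / n
  for (ph in names(props)) {
    se <- sqrt(props[ph] * (1 - props[ph]) / n)
    expect_lt(abs(emp[ph] - props[ph]), 3 * se + 1e-12)
  }
})

test_that("DNA content doubles from G1 to G2/M and markers are bimodal", {
  sc <- generate_colony_scene(scene_params(), seed = 3)
  cl <- sc$cells
  ratio <- mean(cl$dna_int[cl$phase %in% c("G2", "M")]) /
    mean(cl$dna_int[cl$phase == "G1"])
  expect_lt(abs(ratio - 2), 0.15)
  expect_gt(median(cl$edu_mean[cl$phase == "S"]),
            5 * median(cl$edu_mean[cl$phase != "S"]))
  expect_gt(median(cl$ph3_mean[cl$phase == "M"]),
            5 * median(cl$ph3_mean[cl$phase != "M"]))
})

test_that("rendering is linear and fields reproduce the scene", {
  p <- scene_params(n_colonies = 1, cells_per_colony = 30,
                    scene_w_um = 200, scene_h_um = 200, colony_radius_um = 70,
                    colony_glow = 0)
  sc <- generate_colony_scene(p, seed = 5)
  img <- render_scene(sc, "dna")$dna
  ## doubling all amplitudes doubles foreground pixels (noise-free)
  sc2 <- sc
  sc2$cells$dna_int <- 2 * sc2$cells$dna_int
  img2 <- render_scene(sc2, "dna")$dna
  expect_equal(img2, 2 * img, tolerance = 1e-12)

  ## overlap 0: concatenating fields reproduces the whole-scene rendering
  g0 <- grid_spec(2, 2, 100, 100, overlap = 0)
  flds <- render_fields(sc, g0, channels = "dna", noise = FALSE)
  recon <- mosaic_fields(flds, g0, "dna")
  expect_equal(recon, img, tolerance = 1e-12)

  ## per-field gain 2 doubles non-background pixels
  fe <- data.frame(fx = 0, fy = 0, gain = 2, background = 0)
  flds2 <- render_fields(sc, g0, field_effects = fe, channels = "dna",
                         noise = FALSE)
  expect_equal(flds2[[1]]$channels$dna, 2 * flds[[1]]$channels$dna,
               tolerance = 1e-12)
})

test_that("noise-free shared margins agree up to gain and background", {
  p <- scene_params(n_colonies = 1, cells_per_colony = 40,
                    scene_w_um = 180, scene_h_um = 100, colony_radius_um = 35)
  sc <- generate_colony_scene(p, seed = 8)
  g <- grid_spec(2, 1, 100, 100, overlap = 20)
  fe <- data.frame(fx = c(0, 1), fy = 0, gain = c(1, 0.5),
                   background = c(0, 10))
  flds <- render_fields(sc, g, field_effects = fe, channels = "dna",
                        noise = FALSE)
  left_margin_of_f1 <- flds[[2]]$channels$dna[, 1:20]
  right_margin_of_f0 <- flds[[1]]$channels$dna[, 81:100]
  expect_equal(left_margin_of_f1, 0.5 * right_margin_of_f0 + 10,
               tolerance = 1e-9)
})

test_that("a cell in the shared margin appears in both fields at offset step", {
  p <- scene_params(n_colonies = 1, cells_per_colony = 25,
                    scene_w_um = 180, scene_h_um = 100, colony_radius_um = 35)
  g <- grid_spec(2, 1, 100, 100, overlap = 20)
  step <- 100 - 20
  ## find a layout (deterministic seed scan) with a cell in the shared strip
  sc <- NULL
  for (seed in 11:30) {
    cand <- generate_colony_scene(p, seed = seed)
    if (any(cand$cells$x_um > 85 & cand$cells$x_um < 95)) { sc <- cand; break }
  }
  expect_false(is.null(sc))
  cell <- sc$cells[sc$cells$x_um > 85 & sc$cells$x_um < 95, ][1, ]
  flds <- render_fields(sc, g, channels = "dna", noise = FALSE)
  local0 <- round(c(cell$x_um, cell$y_um))          # field (0,0), 1 um/px
  local1 <- local0 - c(step, 0)
  v0 <- flds[[1]]$channels$dna[local0[2], local0[1]]
  v1 <- flds[[2]]$channels$dna[local1[2], local1[1]]
  expect_gt(v0, 0)
  expect_equal(v0, v1, tolerance = 1e-9)
})

test_that("grid that does not cover the scene is rejected", {
  sc <- generate_colony_scene(scene_params(), seed = 1)
  g_small <- grid_spec(1, 1, 300, 300, overlap = 0)
  expect_error(render_fields(sc, g_small, channels = "dna"), "cover")
})
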