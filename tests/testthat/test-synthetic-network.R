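test_that("spec invariants are enforced", {
  expect_error(network_spec(image_width_px = 0), "zero-area")
  expect_error(network_spec(pixel_size = 0), "pixel_size")
  expect_error(network_spec(radius_mixture = list(c(0.2, 0.02, 0.6),
                                                  c(0.4, 0.02, 0.6))),
               "sum to 1")
  expect_error(network_spec(radius_mixture = list(c(-0.2, 0.02, 1))),
               "positive")
  expect_error(network_spec(fiber_length_range = c(10, 5)), "min > max")
})

test_that("empty network gives empty mask and zero ground truth", {
  net <- generate_fiber_network(network_spec(n_fibers = 0L,
                                             image_width_px = 64L,
                                             image_height_px = 64L))
  expect_false(any(net$mask$mask))
  expect_equal(net$truth$true_area_fraction, 0)
  expect_equal(net$truth$true_crosslink_count, 0L)
  expect_equal(net$truth$true_total_length, 0)
})

test_that("identical spec and seed give bit-identical output", {
  sp <- small_network_spec(31L)
  a <- generate_fiber_network(sp)
  b <- generate_fiber_network(sp)
  expect_identical(a$mask$mask, b$mask$mask)
  expect_identical(a$micrograph$intensity, b$micrograph$intensity)
  expect_identical(a$truth$fiber_segments, b$truth$fiber_segments)
})

test_that("crosslink ground truth matches the brute-force ccw oracle", {
  for (seed in c(3L, 17L, 91L)) {
    sp <- small_network_spec(seed, n_fibers = 50L)
    net <- generate_fiber_network(sp)
    W <- sp$image_width_px * sp$pixel_size
    H <- sp$image_height_px * sp$pixel_size
    expect_equal(net$truth$true_crosslink_count,
                 oracle_crossing_count(net$truth$fiber_segments, W, H),
                 info = paste("seed", seed))
  }
})

test_that("drawn radii are bimodal at the default mixture means", {
  sp <- network_spec(n_fibers = 400L, image_width_px = 64L,
                     image_height_px = 64L, seed = 5L)
  net <- generate_fiber_network(sp)
  r <- net$truth$true_radii
  thin <- r[r < 0.255]
  thick <- r[r >= 0.255]
  expect_gt(length(thin), 120)
  expect_gt(length(thick), 120)
  expect_equal(mean(thin), 0.17, tolerance = 0.02)
  expect_equal(mean(thick), 0.34, tolerance = 0.02)
})

test_that("rasterized area fraction matches the closed-form capsule area", {
  # one capsule fully inside a 20x20 um frame
  seg <- data.frame(x1 = 5, y1 = 10, x2 = 15, y2 = 10, r = 1)
  frac <- rasterize_area_fraction(seg, 200, 200, 0.1, supersample_factor = 4)
  expect_equal(frac, oracle_capsule_area(10, 1) / 400, tolerance = 0.01)

  # additivity for disjoint capsules, subadditivity for overlap
  seg2 <- data.frame(x1 = c(5, 5), y1 = c(5, 15), x2 = c(15, 15),
                     y2 = c(5, 15), r = 0.8)
  f_both <- rasterize_area_fraction(seg2, 200, 200, 0.1, 4)
  f1 <- rasterize_area_fraction(seg2[1, ], 200, 200, 0.1, 4)
  f2 <- rasterize_area_fraction(seg2[2, ], 200, 200, 0.1, 4)
  expect_equal(f_both, f1 + f2, tolerance = 1e-12)
  seg3 <- data.frame(x1 = c(5, 10), y1 = c(10, 5), x2 = c(15, 10),
                     y2 = c(10, 15), r = 0.8)
  f_cross <- rasterize_area_fraction(seg3, 200, 200, 0.1, 8)
  g1 <- rasterize_area_fraction(seg3[1, ], 200, 200, 0.1, 8)
  g2 <- rasterize_area_fraction(seg3[2, ], 200, 200, 0.1, 8)
  expect_lt(f_cross, g1 + g2)
  expect_equal(rasterize_area_fraction(seg3[0, ], 200, 200, 0.1), 0)
  expect_error(rasterize_area_fraction(seg, 200, 200, 0.1, 0), "supersample")
})

test_that("network files round-trip through the sidecar format", {
  net <- generate_fiber_network(small_network_spec(8L, n_fibers = 5L,
                                                   side = 120L))
  stem <- file.path(withr::local_tempdir(), "net")
  write_fiber_network(net, stem)
  expect_true(file.exists(paste0(stem, ".pgm")))
  mask <- load_mask(paste0(stem, "_mask.pgm"), net$mask$pixel_size)
  expect_identical(mask$mask, net$mask$mask)
  truth <- jsonlite::read_json(paste0(stem, "_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$true_crosslink_count, net$truth$true_crosslink_count)
  expect_equal(truth$true_area_fraction, net$truth$true_area_fraction)
})
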