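grid_mask <- function(n_bars = 4, size = 101, thick = 3, pixel_size = 0.1) {
  # (n_bars) horizontal x (n_bars) vertical full-span bars -> (n-1)^2
  # interior pores
  m <- matrix(FALSE, size, size)
  at <- round(seq(1, size - thick + 1, length.out = n_bars))
  for (a in at) {
    m[a:(a + thick - 1), ] <- TRUE
    m[, a:(a + thick - 1)] <- TRUE
  }
  binary_mask(m, pixel_size, "manual")
}

test_that("bar-grid pores follow the grid combinatorics", {
  for (n in c(3, 5)) {
    bm <- grid_mask(n_bars = n)
    pores <- find_pores(bm)
    full <- pores[!pores$touches_border, ]
    expect_equal(nrow(full), (n - 1)^2, info = paste("n =", n))
  }
})

test_that("an enclosed 10x10 hole at 0.1 um/px measures 1 um^2", {
  m <- matrix(FALSE, 30, 30)
  m[9:20, 9:20] <- TRUE
  m[10:19, 10:19] <- FALSE  # 10x10 hole
  pores <- find_pores(binary_mask(m, 0.1, "manual"))
  full <- pores[!pores$touches_border, ]
  expect_equal(nrow(full), 1L)
  expect_equal(full$area_um2, 1.0)
})

test_that("pore statistics reproduce hand-countable fractions", {
  pores <- structure(data.frame(id = 1:3, area_um2 = c(2, 3, 7),
                                touches_border = FALSE,
                                centroid_row = 1, centroid_col = 1),
                     class = c("pores", "data.frame"))
  ps <- pore_statistics(pores, bin_width = 5.5 / 3)
  expect_equal(ps$total_full_pores, 3L)
  expect_equal(ps$fraction_dominant, 2 / 3)
  expect_equal(ps$fraction_small, 2 / 3)
  expect_equal(sum(ps$histogram$count), 3)
  # all pores at or above the cutoff
  pores$area_um2 <- c(5.5, 6, 20)
  expect_equal(pore_statistics(pores)$fraction_small, 0)
})

test_that("zero complete pores reports missing fractions, not zeros", {
  m <- matrix(FALSE, 20, 20)  # all background, one border pore
  ps <- pore_statistics(find_pores(binary_mask(m, 0.1, "manual")))
  expect_equal(ps$total_full_pores, 0L)
  expect_true(is.na(ps$fraction_dominant))
  expect_true(is.na(ps$fraction_small))
})

test_that("porosity: trivial cases and conservation with fiber fraction", {
  expect_equal(porosity(binary_mask(matrix(FALSE, 10, 10), 0.1)), 1.0)
  cb <- outer(1:10, 1:10, function(i, j) (i + j) %% 2 == 0)
  expect_equal(porosity(binary_mask(cb, 0.1)), 0.5)
  net <- generate_fiber_network(small_network_spec(29L, n_fibers = 10L,
                                                   side = 250L))
  expect_equal(porosity(net$mask) + mean(net$mask$mask), 1.0)
})

test_that("porosity matches 1 - supersampled area fraction within 1%", {
  net <- generate_fiber_network(small_network_spec(33L, n_fibers = 12L,
                                                   side = 300L))
  af <- rasterize_area_fraction(net$truth$fiber_segments, 300, 300,
                                net$mask$pixel_size, supersample_factor = 4)
  expect_equal(porosity(net$mask), 1 - af, tolerance = 0.01)
})

test_that("complete-pore areas never exceed total background", {
  net <- generate_fiber_network(small_network_spec(37L, n_fibers = 15L,
                                                   side = 300L))
  pores <- find_pores(net$mask)
  bg_area <- sum(!net$mask$mask) * net$mask$pixel_size^2
  expect_lte(sum(pores$area_um2[!pores$touches_border]), bg_area)
  expect_true(all(pores$area_um2 > 0))
})

test_that("enlarging the frame never decreases the complete-pore count", {
  net <- generate_fiber_network(small_network_spec(39L, n_fibers = 20L,
                                                   side = 360L))
  m <- net$mask$mask
  count_full <- function(mm) {
    p <- find_pores(binary_mask(mm, net$mask$pixel_size, "manual"))
    sum(!p$touches_border)
  }
  inner <- count_full(m[61:300, 61:300])
  outer_ <- count_full(m)
  expect_gte(outer_, inner)
})

test_that("layer summary reproduces the published per-layer means", {
  ref <- pore_table_reference()
  tab <- summarize_layers(ref)
  g <- function(layer, stat) tab$mean[tab$layer == layer & tab$statistic == stat]
  expect_equal(g("L-1", "total_full_pores"), 99)
  expect_equal(g("L-3", "total_full_pores"), 51.8)
  expect_equal(round(g("L-1", "porosity"), 2), 0.52)
  expect_equal(round(g("L-3", "porosity"), 2), 0.65)
  expect_equal(round(g("L-3", "fraction_dominant"), 2), 0.32)
  expect_equal(round(g("L-1", "fraction_small"), 2), 0.71)
  # single-image layer: mean equals the value
  one <- summarize_layers(list("L-x" = list(porosity = 0.5)))
  expect_equal(one$mean, 0.5)
  # CSV/JSON emission
  d <- withr::local_tempdir()
  summarize_layers(ref, csv = file.path(d, "t.csv"), json = file.path(d, "t.json"))
  expect_true(file.exists(file.path(d, "t.csv")))
  expect_true(file.exists(file.path(d, "t.json")))
})
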