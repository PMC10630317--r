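# Small programmatic fixtures shared across tests.

px_default <- 0.1  # um/px for hand-built masks

bar_mask <- function(nr = 20, nc = 110, thick = 3, len = 100, pixel_size = px_default) {
  m <- matrix(FALSE, nr, nc)
  r0 <- floor((nr - thick) / 2) + 1
  c0 <- floor((nc - len) / 2) + 1
  m[r0:(r0 + thick - 1), c0:(c0 + len - 1)] <- TRUE
  binary_mask(m, pixel_size, "manual")
}

plus_mask <- function(size = 101, thick = 5, arm = 45, pixel_size = px_default) {
  m <- matrix(FALSE, size, size)
  mid <- (size + 1) / 2
  h <- (thick - 1) / 2
  m[(mid - h):(mid + h), (mid - arm):(mid + arm)] <- TRUE
  m[(mid - arm):(mid + arm), (mid - h):(mid + h)] <- TRUE
  binary_mask(m, pixel_size, "manual")
}

disk_mask <- function(size = 41, radius_px = 10, pixel_size = px_default) {
  mid <- (size + 1) / 2
  d2 <- outer((seq_len(size) - mid)^2, (seq_len(size) - mid)^2, "+")
  binary_mask(d2 <= radius_px^2, pixel_size, "manual")
}

# hollow square loop (fiber frame) fully interior to the image
loop_mask <- function(size = 101, thick = 5, half = 35, pixel_size = px_default) {
  m <- matrix(FALSE, size, size)
  mid <- (size + 1) / 2
  lo <- mid - half; hi <- mid + half
  m[lo:hi, lo:hi] <- TRUE
  m[(lo + thick):(hi - thick), (lo + thick):(hi - thick)] <- FALSE
  binary_mask(m, pixel_size, "manual")
}

# a small fast network spec for pipeline tests
small_network_spec <- function(seed, n_fibers = 12L, side = 400L, ...) {
  network_spec(image_width_px = side, image_height_px = side,
               n_fibers = n_fibers, fiber_length_range = c(4, 12),
               seed = seed, ...)
}

# Seeds for which small_network_spec(seed, 8) yields a "sparse" network:
# every pair of crossings farther apart than 2 um and no fiber endpoint
# within 1 um of another fiber's centreline (verified by the precondition
# assertions where used).
sparse_check <- function(net, min_sep = 2, end_clear = 1, arm_min = 1,
                         min_angle_deg = 20) {
  tr <- net$truth
  segs <- tr$fiber_segments
  xs <- tr$true_crosslinks
  if (nrow(xs) >= 2) {
    D <- as.matrix(dist(xs[, c("x", "y"), drop = FALSE]))
    diag(D) <- Inf
    if (min(D) < min_sep) return(FALSE)
  }
  W <- net$spec$image_width_px * net$spec$pixel_size
  H <- net$spec$image_height_px * net$spec$pixel_size
  # every crossing must be resolvable: all four arms at least arm_min long
  # and the crossing point clear of the frame border
  for (k in seq_len(nrow(xs))) {
    x <- xs[k, "x"]; y <- xs[k, "y"]
    if (x < arm_min || x > W - arm_min || y < arm_min || y > H - arm_min)
      return(FALSE)
    for (f in c(xs[k, "i"], xs[k, "j"])) {
      d1 <- sqrt((x - segs$x1[f])^2 + (y - segs$y1[f])^2)
      d2 <- sqrt((x - segs$x2[f])^2 + (y - segs$y2[f])^2)
      if (min(d1, d2) < arm_min) return(FALSE)
    }
    # near-tangential crossings are not resolvable by any skeleton method
    a1 <- atan2(segs$y2[xs[k, "i"]] - segs$y1[xs[k, "i"]],
                segs$x2[xs[k, "i"]] - segs$x1[xs[k, "i"]])
    a2 <- atan2(segs$y2[xs[k, "j"]] - segs$y1[xs[k, "j"]],
                segs$x2[xs[k, "j"]] - segs$x1[xs[k, "j"]])
    ang <- abs(((a1 - a2) + pi / 2) %% pi - pi / 2)
    if (ang < min_angle_deg * pi / 180) return(FALSE)
  }
  # endpoint clearance from other fibers' centrelines
  pt_seg_d <- function(px_, py_, x1, y1, x2, y2) {
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx^2 + dy^2
    t <- if (L2 > 0) max(0, min(1, ((px_ - x1) * dx + (py_ - y1) * dy) / L2)) else 0
    sqrt((px_ - (x1 + t * dx))^2 + (py_ - (y1 + t * dy))^2)
  }
  W <- net$spec$image_width_px * net$spec$pixel_size
  H <- net$spec$image_height_px * net$spec$pixel_size
  for (f in seq_len(nrow(segs))) {
    for (e in 1:2) {
      ex <- segs[[c("x1", "x2")[e]]][f]; ey <- segs[[c("y1", "y2")[e]]][f]
      if (ex < 0 || ex > W || ey < 0 || ey > H) next
      for (g in seq_len(nrow(segs))) {
        if (g == f) next
        if (pt_seg_d(ex, ey, segs$x1[g], segs$y1[g], segs$x2[g], segs$y2[g]) < end_clear)
          return(FALSE)
      }
    }
  }
  TRUE
}
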