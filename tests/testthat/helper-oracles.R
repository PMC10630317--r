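# Independent brute-force oracles. These deliberately re-derive quantities
# by different algorithms than the package uses.

# Count proper pairwise segment crossings strictly inside the frame, via
# orientation (ccw) tests + determinant intersection point.
oracle_crossing_count <- function(segs, width_um, height_um) {
  ccw <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  n <- nrow(segs)
  cnt <- 0L
  if (n < 2) return(cnt)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d1 <- ccw(segs$x1[i], segs$y1[i], segs$x2[i], segs$y2[i], segs$x1[j], segs$y1[j])
      d2 <- ccw(segs$x1[i], segs$y1[i], segs$x2[i], segs$y2[i], segs$x2[j], segs$y2[j])
      d3 <- ccw(segs$x1[j], segs$y1[j], segs$x2[j], segs$y2[j], segs$x1[i], segs$y1[i])
      d4 <- ccw(segs$x1[j], segs$y1[j], segs$x2[j], segs$y2[j], segs$x2[i], segs$y2[i])
      if (d1 * d2 < 0 && d3 * d4 < 0) {
        t <- d3 / (d3 - d4)
        x <- segs$x1[i] + t * (segs$x2[i] - segs$x1[i])
        y <- segs$y1[i] + t * (segs$y2[i] - segs$y1[i])
        if (x > 0 && x < width_um && y > 0 && y < height_um) cnt <- cnt + 1L
      }
    }
  }
  cnt
}

# Pairwise crossing points (same method), for sparsity preconditions.
oracle_crossing_points <- function(segs, width_um, height_um) {
  pts <- list()
  n <- nrow(segs)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        den <- (segs$x2[i] - segs$x1[i]) * (segs$y2[j] - segs$y1[j]) -
               (segs$y2[i] - segs$y1[i]) * (segs$x2[j] - segs$x1[j])
        if (abs(den) < 1e-12) next
        t <- ((segs$x1[j] - segs$x1[i]) * (segs$y2[j] - segs$y1[j]) -
              (segs$y1[j] - segs$y1[i]) * (segs$x2[j] - segs$x1[j])) / den
        u <- ((segs$x1[j] - segs$x1[i]) * (segs$y2[i] - segs$y1[i]) -
              (segs$y1[j] - segs$y1[i]) * (segs$x2[i] - segs$x1[i])) / den
        if (t > 0 && t < 1 && u > 0 && u < 1) {
          x <- segs$x1[i] + t * (segs$x2[i] - segs$x1[i])
          y <- segs$y1[i] + t * (segs$y2[i] - segs$y1[i])
          if (x > 0 && x < width_um && y > 0 && y < height_um)
            pts[[length(pts) + 1L]] <- c(x = x, y = y, i = i, j = j, t = t, u = u)
        }
      }
    }
  }
  if (length(pts)) do.call(rbind, pts) else
    matrix(numeric(0), ncol = 6, dimnames = list(NULL, c("x", "y", "i", "j", "t", "u")))
}

# Closed-form area of one capsule (rectangle + two half disks).
oracle_capsule_area <- function(length_um, r_um) 2 * r_um * length_um + pi * r_um^2

# Brute-force nearest-background Euclidean distance at one pixel (px units).
oracle_nearest_bg <- function(mask, i, j) {
  bg <- which(!mask, arr.ind = TRUE)
  sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2))
}

# Closed-form single-Gaussian MLE log-likelihood and AIC (p = 2).
oracle_gauss_aic <- function(x) {
  n <- length(x)
  s2 <- mean((x - mean(x))^2)
  ll <- -n / 2 * log(2 * pi * s2) - n / 2
  list(loglik = ll, aic = 2 * 2 - 2 * ll)
}

# Independent Hertz forward force (re-derived, uN/um/kPa convention).
oracle_hertz_force <- function(d_um, E_star_kpa, R_um) {
  ifelse(d_um > 0, 4 / 3 * (E_star_kpa * 1e-3) * R_um^0.5 * d_um^1.5, 0)
}

# Along-fiber spacing oracle for l_c: for every fiber, the distances between
# consecutive crossing points along it (plus crossing-to-free-end stubs for
# in-frame ends), restricted to spans lying fully inside the frame.
oracle_segment_spacings <- function(segs, width_um, height_um) {
  pts <- oracle_crossing_points(segs, width_um, height_um)
  spac <- numeric(0)
  inside <- function(x, y) x > 0 & x < width_um & y > 0 & y < height_um
  for (f in seq_len(nrow(segs))) {
    tpar <- sort(c(pts[pts[, "i"] == f, "t"], pts[pts[, "j"] == f, "u"]))
    if (length(tpar) == 0) next
    L <- sqrt((segs$x2[f] - segs$x1[f])^2 + (segs$y2[f] - segs$y1[f])^2)
    ends_in <- c(inside(segs$x1[f], segs$y1[f]), inside(segs$x2[f], segs$y2[f]))
    knots <- tpar
    if (ends_in[1]) knots <- c(0, knots)
    if (ends_in[2]) knots <- c(knots, 1)
    px <- segs$x1[f] + knots * (segs$x2[f] - segs$x1[f])
    py <- segs$y1[f] + knots * (segs$y2[f] - segs$y1[f])
    for (k in seq_len(length(knots) - 1)) {
      # keep the span only if its midpoint stays in frame (no border crossing)
      mx <- (px[k] + px[k + 1]) / 2; my <- (py[k] + py[k + 1]) / 2
      if (inside(px[k], py[k]) && inside(px[k + 1], py[k + 1]) && inside(mx, my))
        spac <- c(spac, (knots[k + 1] - knots[k]) * L)
    }
  }
  spac
}
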