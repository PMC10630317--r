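#' Specification of a synthetic fiber network
#'
#' Describes a random network of straight cylindrical hyphae (rendered as 2-D
#' capsules: thick line segments with round caps) used to emulate SEM
#' micrographs of mycelium. Radii are drawn from a Gaussian mixture whose
#' default components mimic the two thin dominant hyphal types found at every
#' growth depth (means 0.17 and 0.34 um); fiber centres and orientations are
#' uniform, lengths uniform in `fiber_length_range`.
#'
#' @param image_width_px,image_height_px image size in pixels.
#' @param pixel_size um per pixel. The default 0.033 gives the thinnest
#'   default fiber type (radius 0.17 um) a ~10 px diameter, safely above the
#'   few-pixels-per-diameter resolution floor where radius estimation breaks.
#' @param n_fibers number of fibers.
#' @param radius_mixture list of `c(mean_um, sd_um, weight)` triples; weights
#'   must sum to 1.
#' @param fiber_length_range `c(min, max)` fiber length in um.
#' @param orientation `"uniform"` (isotropic angles) is the only option.
#' @param depth_layers number of depth (shading) layers used for grayscale
#'   rendering; fibers in deeper layers are drawn dimmer, as in SEM depth
#'   cueing.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(image_width_px = 800L, image_height_px = 800L,
                         pixel_size = 0.033, n_fibers = 30L,
                         radius_mixture = list(c(0.17, 0.015, 0.5),
                                               c(0.34, 0.030, 0.5)),
                         fiber_length_range = c(5, 30),
                         orientation = "uniform",
                         depth_layers = 3L, seed = 1L) {
  if (image_width_px < 1 || image_height_px < 1)
    stop("network_spec: zero-area image", call. = FALSE)
  if (pixel_size <= 0)
    stop("network_spec: pixel_size must be positive", call. = FALSE)
  if (n_fibers < 0) stop("network_spec: n_fibers must be >= 0", call. = FALSE)
  mix <- do.call(rbind, lapply(radius_mixture, function(m) {
    stopifnot(length(m) == 3L)
    m
  }))
  colnames(mix) <- c("mean", "sd", "weight")
  if (abs(sum(mix[, "weight"]) - 1) > 1e-9)
    stop("network_spec: mixture weights must sum to 1", call. = FALSE)
  if (any(mix[, "mean"] <= 0) || any(mix[, "sd"] <= 0))
    stop("network_spec: mixture means and sds must be positive", call. = FALSE)
  if (fiber_length_range[1] > fiber_length_range[2])
    stop("network_spec: fiber_length_range min > max", call. = FALSE)
  structure(list(image_width_px = as.integer(image_width_px),
                 image_height_px = as.integer(image_height_px),
                 pixel_size = pixel_size, n_fibers = as.integer(n_fibers),
                 radius_mixture = mix,
                 fiber_length_range = fiber_length_range,
                 orientation = orientation,
                 depth_layers = as.integer(depth_layers),
                 seed = as.integer(seed)),
            class = "network_spec")
}

# Draw fiber centreline geometry (um coordinates) for a spec. Pure geometry;
# separated from rasterisation so density calibration can run cheaply.
draw_fiber_geometry <- function(spec) {
  W <- spec$image_width_px * spec$pixel_size
  H <- spec$image_height_px * spec$pixel_size
  n <- spec$n_fibers
  if (n == 0L)
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), r = numeric(0), depth = integer(0)))
  mix <- spec$radius_mixture
  comp <- sample.int(nrow(mix), n, replace = TRUE, prob = mix[, "weight"])
  r <- rnorm(n, mix[comp, "mean"], mix[comp, "sd"])
  # resample non-positive radii (vanishing probability at default sds)
  while (any(r <= 0)) {
    bad <- which(r <= 0)
    r[bad] <- rnorm(length(bad), mix[comp[bad], "mean"], mix[comp[bad], "sd"])
  }
  len <- runif(n, spec$fiber_length_range[1], spec$fiber_length_range[2])
  ang <- runif(n, 0, pi)
  cx <- runif(n, 0, W)
  cy <- runif(n, 0, H)
  depth <- sample.int(spec$depth_layers, n, replace = TRUE)
  data.frame(x1 = cx - len / 2 * cos(ang), y1 = cy - len / 2 * sin(ang),
             x2 = cx + len / 2 * cos(ang), y2 = cy + len / 2 * sin(ang),
             r = r, depth = depth)
}

# All interior pairwise centreline intersections. Strict crossings only
# (parameters in the open interval) at points strictly inside the frame,
# mirroring the edge-exclusion policy used for measured crosslinks.
segment_intersections <- function(segs, width_um, height_um) {
  n <- nrow(segs)
  out <- matrix(numeric(0), ncol = 4,
                dimnames = list(NULL, c("x", "y", "i", "j")))
  if (n < 2) return(out)
  acc <- vector("list", 0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d1x <- segs$x2[i] - segs$x1[i]; d1y <- segs$y2[i] - segs$y1[i]
      d2x <- segs$x2[j] - segs$x1[j]; d2y <- segs$y2[j] - segs$y1[j]
      den <- d1x * d2y - d1y * d2x
      if (abs(den) < 1e-12) next  # parallel/collinear: no transversal crossing
      ex <- segs$x1[j] - segs$x1[i]; ey <- segs$y1[j] - segs$y1[i]
      t <- (ex * d2y - ey * d2x) / den
      u <- (ex * d1y - ey * d1x) / den
      if (t <= 0 || t >= 1 || u <= 0 || u >= 1) next
      x <- segs$x1[i] + t * d1x; y <- segs$y1[i] + t * d1y
      if (x <= 0 || x >= width_um || y <= 0 || y >= height_um) next
      acc[[length(acc) + 1L]] <- c(x, y, i, j)
    }
  }
  if (length(acc)) out <- do.call(rbind, acc)
  colnames(out) <- c("x", "y", "i", "j")
  out
}

# Liang-Barsky clipping: length of a segment inside [0,W]x[0,H].
clip_length <- function(x1, y1, x2, y2, W, H) {
  dx <- x2 - x1; dy <- y2 - y1
  p <- c(-dx, dx, -dy, dy)
  q <- c(x1, W - x1, y1, H - y1)
  t0 <- 0; t1 <- 1
  for (k in 1:4) {
    if (p[k] == 0) {
      if (q[k] < 0) return(0)
    } else {
      t <- q[k] / p[k]
      if (p[k] < 0) t0 <- max(t0, t) else t1 <- min(t1, t)
    }
  }
  if (t0 >= t1) return(0)
  (t1 - t0) * sqrt(dx^2 + dy^2)
}

#' Generate a synthetic fiber-network micrograph with ground truth
#'
#' Renders the fibers of a [network_spec()] as capsules into (i) a grayscale
#' micrograph with depth-cued shading and (ii) the exact rasterized binary
#' mask, and attaches analytic ground truth: centrelines with radii, the
#' count of interior pairwise centreline intersections, total in-frame
#' centreline length, and the rasterized fiber area fraction.
#'
#' @param spec a [network_spec()].
#' @return A list of class `fiber_network` with elements `micrograph`
#'   (class `micrograph`), `mask` (class `binary_mask`), and `truth` (class
#'   `network_truth` with fields `fiber_segments`, `true_crosslink_count`,
#'   `true_crosslinks`, `true_total_length`, `true_radii`,
#'   `true_area_fraction`).
#' @export
generate_fiber_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(spec$seed)
  segs <- draw_fiber_geometry(spec)
  W <- spec$image_width_px * spec$pixel_size
  H <- spec$image_height_px * spec$pixel_size
  nr <- spec$image_height_px; nc <- spec$image_width_px

  if (nrow(segs) == 0L) {
    mask <- matrix(FALSE, nr, nc)
    gray <- matrix(30L, nr, nc)
  } else {
    segm <- as.matrix(segs[, c("x1", "y1", "x2", "y2", "r")])
    mask <- cpp_capsule_mask(segm, nr, nc, spec$pixel_size)
    # grayscale: deepest layer first, each shallower layer brighter
    gray <- matrix(30L, nr, nc)
    shades <- round(seq(120, 235, length.out = spec$depth_layers))
    for (d in seq(spec$depth_layers, 1)) {
      sel <- segs$depth == d
      if (!any(sel)) next
      lm_ <- cpp_capsule_mask(as.matrix(segs[sel, c("x1", "y1", "x2", "y2", "r")]),
                              nr, nc, spec$pixel_size)
      gray[lm_] <- shades[spec$depth_layers - d + 1L]
    }
  }

  xs <- if (nrow(segs)) segment_intersections(segs, W, H) else
    matrix(numeric(0), ncol = 4, dimnames = list(NULL, c("x", "y", "i", "j")))
  total_len <- if (nrow(segs))
    sum(mapply(clip_length, segs$x1, segs$y1, segs$x2, segs$y2,
               MoreArgs = list(W = W, H = H))) else 0

  truth <- structure(list(fiber_segments = segs,
                          true_crosslink_count = nrow(xs),
                          true_crosslinks = xs,
                          true_total_length = total_len,
                          true_radii = segs$r,
                          true_area_fraction = mean(mask)),
                     class = "network_truth")
  structure(list(micrograph = micrograph(gray, spec$pixel_size,
                                         source = sprintf("synthetic seed=%d", spec$seed)),
                 mask = binary_mask(mask, spec$pixel_size, "automatic"),
                 truth = truth, spec = spec),
            class = "fiber_network")
}

#' @export
print.fiber_network <- function(x, ...) {
  cat(sprintf("<fiber_network> %d fibers, %d interior crosslinks, area fraction %.3f\n",
              nrow(x$truth$fiber_segments), x$truth$true_crosslink_count,
              x$truth$true_area_fraction))
  invisible(x)
}

#' Rasterized area fraction of a capsule union
#'
#' Supersampled pixel-counting estimate of the area fraction covered by a set
#' of capsules within the image frame. Converges monotonically in accuracy as
#' `supersample_factor` grows; used as the porosity oracle for synthetic
#' networks.
#'
#' @param segments data frame with columns `x1, y1, x2, y2, r` in um.
#' @param nrow_px,ncol_px frame size in pixels.
#' @param pixel_size um per pixel.
#' @param supersample_factor integer >= 1; each pixel is subdivided into
#'   `supersample_factor^2` test points.
#' @return Dimensionless fraction in `[0, 1]`.
#' @export
rasterize_area_fraction <- function(segments, nrow_px, ncol_px, pixel_size,
                                    supersample_factor = 4L) {
  if (supersample_factor < 1) stop("supersample_factor must be >= 1", call. = FALSE)
  if (is.null(segments) || nrow(segments) == 0L) return(0.0)
  segm <- as.matrix(segments[, c("x1", "y1", "x2", "y2", "r")])
  cpp_capsule_coverage(segm, as.integer(nrow_px), as.integer(ncol_px),
                       pixel_size, as.integer(supersample_factor))
}

#' Write a fiber network to disk
#'
#' Emits `<stem>.pgm` (grayscale micrograph), `<stem>_mask.pgm` (binary mask)
#' and `<stem>_truth.json` (ground-truth sidecar).
#'
#' @param net a `fiber_network`.
#' @param stem output path stem.
#' @export
write_fiber_network <- function(net, stem) {
  write_image(net$micrograph, paste0(stem, ".pgm"))
  write_image(net$mask, paste0(stem, "_mask.pgm"))
  tr <- net$truth
  jsonlite::write_json(list(true_crosslink_count = tr$true_crosslink_count,
                            true_total_length = tr$true_total_length,
                            true_area_fraction = tr$true_area_fraction,
                            true_radii = tr$true_radii,
                            fiber_segments = tr$fiber_segments,
                            pixel_size = net$mask$pixel_size),
                       paste0(stem, "_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}
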