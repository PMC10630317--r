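#' Binarize a micrograph into a fiber/background mask
#'
#' Converts a grayscale micrograph to a logical fiber mask by one of three
#' thresholding families, then optionally removes small speckle components.
#' Mirrors the practice of running several segmentation algorithms on the
#' same micrograph and picking per descriptor: the chosen method is recorded
#' in the mask provenance (`"automatic"`); externally produced manual masks
#' enter through [load_mask()] instead.
#'
#' @param m a [micrograph()].
#' @param method `"global-otsu"` (default), `"adaptive-mean"` (local mean
#'   threshold over a square window) or `"fixed"`.
#' @param threshold intensity threshold for `method = "fixed"`; pixels with
#'   intensity `>= threshold` become fiber.
#' @param window_px window size (odd, pixels) for `"adaptive-mean"`.
#' @param offset added to the local mean before comparison
#'   (`"adaptive-mean"`).
#' @param min_object_area_um2 connected fiber components smaller than this
#'   are removed as speckle noise (default 0.05 um^2); set 0 to disable.
#' @return A [binary_mask()] with provenance `"automatic"`.
#' @export
binarize <- function(m, method = c("global-otsu", "adaptive-mean", "fixed"),
                     threshold = NULL, window_px = 31L, offset = 0,
                     min_object_area_um2 = 0.05) {
  stopifnot(inherits(m, "micrograph"))
  method <- match.arg(method)
  img <- m$intensity
  fg <- switch(method,
    "global-otsu" = {
      if (min(img) == max(img)) {
        warning("binarize: constant-intensity image; Otsu is degenerate, ",
                "returning all-background")
        matrix(FALSE, nrow(img), ncol(img))
      } else {
        img >= otsu_threshold(img)
      }
    },
    "adaptive-mean" = {
      lm_ <- local_mean(img, window_px)
      img >= lm_ + offset
    },
    "fixed" = {
      if (is.null(threshold))
        stop("binarize: method 'fixed' needs a threshold", call. = FALSE)
      if (threshold < 0 || threshold > max(img, 255))
        stop("binarize: fixed threshold outside intensity range", call. = FALSE)
      img >= threshold
    })
  if (min_object_area_um2 > 0 && any(fg)) {
    min_px <- min_object_area_um2 / m$pixel_size^2
    lab <- cpp_label(fg, 8L)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_px)
    if (length(drop)) fg[lab %in% drop] <- FALSE
  }
  binary_mask(fg, m$pixel_size, "automatic")
}

# Otsu's between-class-variance-maximising global threshold on a 256-bin
# histogram; returns the threshold intensity (foreground = intensity >= t).
otsu_threshold <- function(img) {
  rng <- range(img)
  # map to 0..255 bins over the observed range
  bins <- pmin(255L, pmax(0L, as.integer(floor((img - rng[1]) /
                                                 (rng[2] - rng[1]) * 256))))
  h <- as.numeric(tabulate(bins + 1L, nbins = 256L))
  w <- cumsum(h)
  mu <- cumsum(h * (0:255))
  tot <- w[256]; mu_t <- mu[256]
  w0 <- w[1:255]; w1 <- tot - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, 255)
  between[valid] <- (mu_t * w0[valid] - mu[1:255][valid])^2 /
    (w0[valid] * w1[valid])
  k <- which.max(between)  # threshold bin: foreground = bin > k-1
  rng[1] + k / 256 * (rng[2] - rng[1])
}

# Local mean via integral image (zero-padded window truncation at borders).
local_mean <- function(img, window_px) {
  if (window_px %% 2L == 0L) window_px <- window_px + 1L
  h <- (window_px - 1L) / 2L
  nr <- nrow(img); nc <- ncol(img)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1, -1] <- apply(apply(img, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    a <- S[r2 + 1L, c2[j] + 1L] - S[r1, c2[j] + 1L] -
         S[r2 + 1L, c1[j]] + S[r1, c1[j]]
    n <- (r2 - r1 + 1L) * (c2[j] - c1[j] + 1L)
    out[, j] <- a / n
  }
  out
}

#' Load a manual segmentation mask from disk
#'
#' Reads a single-channel PGM image and interprets every nonzero pixel as
#' fiber, standing in for manually annotated segmentations. Provenance is
#' tagged `"manual"`.
#'
#' @param path path to a single-channel PGM file.
#' @param pixel_size um per pixel of the originating micrograph.
#' @param expect_dim optional `c(nrow, ncol)`; a mismatch is an error naming
#'   both shapes.
#' @return A [binary_mask()] with provenance `"manual"`.
#' @export
load_mask <- function(path, pixel_size, expect_dim = NULL) {
  img <- read_pgm(path)
  if (!is.null(expect_dim) &&
      !(nrow(img) == expect_dim[1] && ncol(img) == expect_dim[2]))
    stop(sprintf("load_mask: image is %d x %d but %d x %d was expected",
                 nrow(img), ncol(img), expect_dim[1], expect_dim[2]),
         call. = FALSE)
  binary_mask(img != 0, pixel_size, "manual")
}
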