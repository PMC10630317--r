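#' Micrograph and binary-mask containers
#'
#' A `micrograph` wraps an integer intensity matrix (8- or 16-bit range) with
#' the physical pixel size; a `binary_mask` wraps a logical matrix (`TRUE` =
#' fiber) with the same pixel size and a provenance tag recording whether the
#' segmentation was automatic or manual. Rows index the vertical (y) axis,
#' columns the horizontal (x) axis, origin at the top-left; pixel `[i, j]` is
#' centred at physical coordinates `x = (j - 0.5) * pixel_size`,
#' `y = (i - 0.5) * pixel_size` micrometres.
#'
#' @param intensity integer-valued matrix of pixel intensities.
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @param source free-form identifier of where the image came from.
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(intensity, pixel_size, source = "unknown") {
  intensity <- as.matrix(intensity)
  if (length(intensity) == 0L || nrow(intensity) == 0L || ncol(intensity) == 0L)
    stop("micrograph: intensity grid must be non-empty", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("micrograph: pixel_size must be a single positive number (um/px)",
         call. = FALSE)
  structure(list(intensity = intensity, pixel_size = pixel_size,
                 source = source),
            class = "micrograph")
}

#' @param mask logical matrix, `TRUE` on fiber pixels.
#' @param provenance `"automatic"` or `"manual"`.
#' @rdname micrograph
#' @export
binary_mask <- function(mask, pixel_size, provenance = c("automatic", "manual")) {
  provenance <- match.arg(provenance)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("binary_mask: pixel_size must be a single positive number (um/px)",
         call. = FALSE)
  structure(list(mask = mask, pixel_size = pixel_size, provenance = provenance),
            class = "binary_mask")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px @ %.4g um/px (%s), range [%d, %d]\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size, x$source,
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px @ %.4g um/px, %s, %.1f%% fiber\n",
              nrow(x$mask), ncol(x$mask), x$pixel_size, x$provenance,
              100 * mean(x$mask)))
  invisible(x)
}

# Frame area in um^2 of any object carrying a pixel grid.
frame_area_um2 <- function(x) {
  g <- if (inherits(x, "micrograph")) x$intensity else x$mask
  nrow(g) * ncol(g) * x$pixel_size^2
}

#' Read and write portable graymap (PGM) images
#'
#' Plain-text (P2) and binary (P5) portable graymaps are used for all image
#' I/O: the format is self-describing, dependency-free, and round-trips 8-bit
#' grayscale exactly. Binary masks are stored as graymaps with values 0 and
#' `maxval`.
#'
#' @param path file path.
#' @return `read_pgm` returns an integer matrix (rows = image rows).
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5"))
    stop("read_pgm: not a P2/P5 portable graymap: ", path, call. = FALSE)
  # header tokens, skipping comments
  tokens <- integer(0)
  buf <- character(0)
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("read_pgm: truncated header", call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      next
    }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf) > 0L) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
      if (length(tokens) == 3L) break
    }
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  if (magic == "P5") {
    raw <- readBin(con, "integer", n = w * h, size = if (maxval < 256) 1L else 2L,
                   signed = FALSE, endian = "big")
    m <- matrix(raw, nrow = h, ncol = w, byrow = TRUE)
  } else {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
    m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  }
  attr(m, "maxval") <- maxval
  m
}

#' @param img integer matrix (or logical matrix for masks).
#' @param maxval maximum gray value declared in the header.
#' @param ascii write plain-text P2 (default) or binary P5.
#' @rdname read_pgm
#' @export
write_pgm <- function(img, path, maxval = 255L, ascii = TRUE) {
  if (is.logical(img)) img <- img * maxval
  img <- round(img)
  storage.mode(img) <- "integer"
  if (any(img < 0L) || any(img > maxval))
    stop("write_pgm: values outside [0, maxval]", call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  if (ascii) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), as.character(maxval)), con)
    # one image row per line
    rows <- apply(img, 1L, paste, collapse = " ")
    writeLines(rows, con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(w, h), as.character(maxval)), con)
    writeBin(as.integer(t(img)), con, size = if (maxval < 256) 1L else 2L,
             endian = "big")
  }
  invisible(path)
}

#' Write a micrograph or mask to disk
#'
#' @param x a `micrograph` or `binary_mask`.
#' @param path destination PGM path.
#' @param ... passed to [write_pgm()].
#' @export
write_image <- function(x, path, ...) {
  if (inherits(x, "micrograph")) write_pgm(x$intensity, path, ...)
  else if (inherits(x, "binary_mask")) write_pgm(x$mask, path, ...)
  else stop("write_image: unsupported object", call. = FALSE)
}
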