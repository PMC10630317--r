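#' Identify pores in a binary mask
#'
#' Pores are 4-connected components of background enclosed by 8-connected
#' fibers (the standard connectivity duality, preventing leak-through at
#' diagonal fiber crossings). Components touching the frame border are
#' flagged `touches_border` - partial pores at the micrograph edge are never
#' silently dropped, only flagged, so callers can exclude them when counting
#' complete pores.
#'
#' @param mask a [binary_mask()].
#' @return Data frame of class `pores`: `id, area_um2, touches_border,
#'   centroid_row, centroid_col`, with attribute `pixel_size`.
#' @export
find_pores <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  bg <- !mask$mask
  lab <- cpp_label(bg, 4L)
  n <- max(lab)
  if (n == 0L) {
    out <- data.frame(id = integer(0), area_um2 = numeric(0),
                      touches_border = logical(0), centroid_row = numeric(0),
                      centroid_col = numeric(0))
  } else {
    idx <- which(bg, arr.ind = TRUE)
    ids <- lab[bg]
    area <- tabulate(ids, nbins = n) * mask$pixel_size^2
    nr <- nrow(bg); nc <- ncol(bg)
    border_ids <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
    out <- data.frame(id = seq_len(n), area_um2 = area,
                      touches_border = seq_len(n) %in% border_ids,
                      centroid_row = as.numeric(tapply(idx[, 1], ids, mean)),
                      centroid_col = as.numeric(tapply(idx[, 2], ids, mean)))
  }
  attr(out, "pixel_size") <- mask$pixel_size
  class(out) <- c("pores", "data.frame")
  out
}

#' Pore-area statistics over complete pores
#'
#' Builds a pore-area histogram over complete (non-border) pores and reports
#' the fraction of dominant pores (the histogram bin containing
#' `dominant_bin_center`) and the fraction of small pores (area below
#' `small_cutoff`). The default bin width of `5.5/3` um^2 makes the first
#' three bins span exactly `[0, 5.5)` um^2 with the second bin centred at
#' 2.75 um^2, so "dominant bin" and "small pores = first three bins" are
#' mutually consistent.
#'
#' @param pores a [find_pores()] result.
#' @param bin_width histogram bin width in um^2.
#' @param small_cutoff small-pore area cutoff, um^2.
#' @param dominant_bin_center area identifying the dominant bin, um^2.
#' @return Object of class `pore_summary`: list with `total_full_pores`,
#'   `fraction_dominant`, `fraction_small`, `histogram` (data frame
#'   `bin_low, bin_high, count`), plus the settings. Fractions are `NA` when
#'   no complete pore exists.
#' @export
pore_statistics <- function(pores, bin_width = 5.5 / 3, small_cutoff = 5.5,
                            dominant_bin_center = 2.75) {
  stopifnot(inherits(pores, "pores"))
  full <- pores$area_um2[!pores$touches_border]
  total <- length(full)
  if (total == 0L) {
    hist_df <- data.frame(bin_low = numeric(0), bin_high = numeric(0),
                          count = integer(0))
    fd <- fs <- NA_real_
  } else {
    nb <- ceiling(max(full) / bin_width)
    bin <- pmin(nb, floor(full / bin_width) + 1L)  # right-closed top bin
    counts <- tabulate(bin, nbins = nb)
    hist_df <- data.frame(bin_low = (seq_len(nb) - 1) * bin_width,
                          bin_high = seq_len(nb) * bin_width,
                          count = counts)
    dom_bin <- floor(dominant_bin_center / bin_width) + 1L
    fd <- if (dom_bin <= nb) counts[dom_bin] / total else 0
    fs <- sum(full < small_cutoff) / total
  }
  structure(list(total_full_pores = total, fraction_dominant = fd,
                 fraction_small = fs, histogram = hist_df,
                 bin_width = bin_width, small_cutoff = small_cutoff,
                 dominant_bin_center = dominant_bin_center),
            class = "pore_summary")
}

#' @export
print.pore_summary <- function(x, ...) {
  cat(sprintf("<pore_summary> %d full pores, dominant fraction %s, small fraction %s\n",
              x$total_full_pores,
              if (is.na(x$fraction_dominant)) "NA" else sprintf("%.2f", x$fraction_dominant),
              if (is.na(x$fraction_small)) "NA" else sprintf("%.2f", x$fraction_small)))
  invisible(x)
}

#' Porosity of a mask
#'
#' Ratio of total pore (background) area to the full micrograph area, with
#' no border exclusion; the complement of the fiber area fraction.
#'
#' @param mask a [binary_mask()].
#' @return Dimensionless porosity in `[0, 1]`.
#' @export
porosity <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  mean(!mask$mask)
}

#' Aggregate per-layer statistic vectors into a summary table
#'
#' Takes, for each growth layer, named numeric vectors of per-micrograph
#' statistics and emits the layer-by-statistic table of values and means
#' (the Table-1-style summary). Ragged inputs are allowed; means run over
#' the available images.
#'
#' @param values_by_layer named list (layer label -> named list of numeric
#'   vectors, one per statistic).
#' @param csv,json optional output paths.
#' @return Data frame with columns `layer, statistic, n, mean, values`
#'   (values as a semicolon-joined string).
#' @export
summarize_layers <- function(values_by_layer, csv = NULL, json = NULL) {
  if (length(values_by_layer) < 1L)
    stop("summarize_layers: at least one layer required", call. = FALSE)
  rows <- list()
  for (layer in names(values_by_layer)) {
    stats_ <- values_by_layer[[layer]]
    for (stat in names(stats_)) {
      v <- stats_[[stat]]
      rows[[length(rows) + 1L]] <-
        data.frame(layer = layer, statistic = stat, n = length(v),
                   mean = mean(v),
                   values = paste(v, collapse = ";"),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(csv)) write.csv(out, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(values_by_layer, json, auto_unbox = TRUE, digits = NA)
  out
}

#' Reference pore-characteristics table
#'
#' The published per-layer pore characteristics of the mycelium tissue:
#' five-micrograph vectors of full-pore counts, dominant- and small-pore
#' fractions and porosity for growth layers L-1 (oldest) to L-3 (youngest),
#' shipped as plain CSV in `extdata`. Used as the reference input for the
#' aggregation checks.
#'
#' @return Named list (layer -> named list of numeric vectors) suitable for
#'   [summarize_layers()].
#' @export
pore_table_reference <- function() {
  path <- system.file("extdata", "pore_characteristics.csv",
                      package = "mycelnet", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(df))) {
    v <- as.numeric(strsplit(df$values[i], ";")[[1]])
    out[[df$layer[i]]][[df$statistic[i]]] <- v
  }
  out
}
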