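#' Sample fiber radii along the skeleton, excluding junction zones
#'
#' One radius sample per centerline pixel: the distance-map value minus half
#' a pixel (the distance transform measures to the nearest background pixel
#' *center*; the fiber interface lies half a pixel closer). Pixels inside the
#' junction exclusion zone - closer than `exclusion_factor` times the local
#' junction radius to any junction centroid - carry no radius information
#' (the nearest interface there no longer reflects a fiber diameter) and are
#' skipped, as are the junction pixels themselves.
#'
#' @param sk a [skeletonize()] result.
#' @param dm the matching [distance_map()] (um).
#' @param exclusion_factor multiple of the junction's local radius defining
#'   the exclusion zone (default 2).
#' @return Object of class `radius_samples`: numeric vector of radii in um
#'   with attributes `n_excluded` (junction-zone centerline pixels skipped)
#'   and `pixel_size`.
#' @export
radius_samples <- function(sk, dm, exclusion_factor = 2) {
  stopifnot(inherits(sk, "skeleton"))
  if (!all(dim(dm) == dim(sk$pixels)))
    stop("radius_samples: distance map and skeleton differ in shape",
         call. = FALSE)
  px <- sk$pixel_size
  eligible <- sk$pixels
  # drop branch-cluster pixels themselves
  cn <- cpp_crossing_number(sk$pixels)
  eligible[cn >= 3L] <- FALSE
  idx <- which(eligible, arr.ind = TRUE)
  n0 <- nrow(idx)
  if (n0 > 0 && nrow(sk$junctions) > 0) {
    keep <- rep(TRUE, n0)
    for (k in seq_len(nrow(sk$junctions))) {
      jr <- sk$junctions$row[k]; jc <- sk$junctions$col[k]
      rad_px <- exclusion_factor * sk$junctions$radius_um[k] / px
      d2 <- (idx[, 1] - jr)^2 + (idx[, 2] - jc)^2
      keep <- keep & d2 > rad_px^2
    }
    idx <- idx[keep, , drop = FALSE]
  }
  vals <- pmax(dm[idx] - px / 2, px / 2)
  if (length(vals) == 0L)
    warning("radius_samples: no eligible centerline pixels")
  structure(vals, class = "radius_samples",
            n_excluded = n0 - length(vals), pixel_size = px)
}

#' @export
print.radius_samples <- function(x, ...) {
  cat(sprintf("<radius_samples> n = %d (excluded %d junction-zone px), mean %.3f um\n",
              length(x), attr(x, "n_excluded"), mean(unclass(x))))
  invisible(x)
}

#' Crosslink (intersection) density of a skeleton
#'
#' Counts fiber-fiber intersections per unit micrograph area. Each junction
#' (merged branch cluster with at least three incident arms) contributes an
#' intersection multiplicity derived from its arm count: a transversal
#' crossing has 4 arms and every additional coincident crossing adds 2, so a
#' junction with `b` arms counts as `max(1, round((b - 2) / 2))`
#' intersections. On sparse networks (every junction an isolated X or T)
#' this reduces to the plain junction count; on dense networks it recovers
#' crossings merged into one cluster, the way a manual annotator counts
#' them.
#'
#' @param sk a [skeletonize()] result.
#' @param analysis_area_um2 area of the analysed frame in um^2.
#' @param bridge_max_um junction-to-junction segments shorter than this are
#'   bridges inside one crossing complex (default 3 um, the resolvability
#'   scale below which the Y-points of one shallow-angle crossing can lie).
#'   Because every crossing contributes four arm slots and every internal
#'   bridge consumes two, the component count is invariant to merging
#'   genuinely distinct crossings, so a generous bridge scale is safe.
#' @param spur_min_um endpoint-terminated arms shorter than this do not
#'   count as arms (default 0: short free arms near a junction proved to be
#'   mostly genuine fiber ends, so nothing is filtered by default).
#' @return List with `junctions` (data frame), `crosslink_count` and
#'   `rho_b` (um^-2).
#' @export
detect_crosslinks <- function(sk, analysis_area_um2, bridge_max_um = 2.5,
                              spur_min_um = 0) {
  stopifnot(inherits(sk, "skeleton"))
  if (analysis_area_um2 <= 0)
    stop("detect_crosslinks: analysis area must be positive", call. = FALSE)
  jn <- sk$junctions
  seg <- sk$segments
  n_j <- nrow(jn)
  count <- 0L
  if (n_j > 0) {
    # arms per junction, dropping spur artifacts (short endpoint-terminated
    # stubs left by thinning)
    arms <- integer(n_j)
    is_spur <- !seg$closed &
      ((is.na(seg$from) & !is.na(seg$to)) | (!is.na(seg$from) & is.na(seg$to))) &
      seg$length_um < spur_min_um
    for (i in seq_len(nrow(seg))) {
      if (seg$closed[i] || is_spur[i]) next
      if (!is.na(seg$from[i])) arms[seg$from[i]] <- arms[seg$from[i]] + 1L
      if (!is.na(seg$to[i])) {
        # self-loop contributes both its termini to the same junction
        arms[seg$to[i]] <- arms[seg$to[i]] + 1L
      }
    }
    # bridge edges: short junction-junction segments joining two 3-arm
    # junctions - the signature of a shallow-angle crossing thinned into a
    # pair of Y-points (a genuine 4-arm crossing chain is not pooled)
    bridge <- !seg$closed & !is.na(seg$from) & !is.na(seg$to) &
      seg$from != seg$to & seg$length_um < bridge_max_um &
      arms[ifelse(is.na(seg$from), 1L, seg$from)] == 3L &
      arms[ifelse(is.na(seg$to), 1L, seg$to)] == 3L
    parent <- seq_len(n_j)
    findr <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    for (i in which(bridge)) {
      ra <- findr(seg$from[i]); rb <- findr(seg$to[i])
      if (ra != rb) parent[ra] <- rb
    }
    comp <- vapply(seq_len(n_j), findr, integer(1))
    for (cp in unique(comp)) {
      members <- which(comp == cp)
      # spanning-tree edge count: exact for chains and robust to bridge
      # cycles (each extra cycle edge would otherwise eat two arms)
      m <- length(members) - 1L
      b_ext <- sum(arms[members]) - 2L * m
      count <- count + max(1L, round((b_ext - 2) / 2))
    }
  }
  list(junctions = jn, crosslink_count = as.integer(count),
       rho_b = count / analysis_area_um2)
}

#' Segment statistics and mean segment length
#'
#' Decomposes the skeleton into branches between junctions/endpoints
#' (already done by [skeletonize()]), excludes incomplete branches touching
#' the micrograph boundary and closed cycles, and averages the lengths that
#' fall inside the length window. The default window of 1-10 um excludes
#' few-pixel artifacts (< 1 um) and non-representative long segments
#' (> 10 um).
#'
#' @param sk a [skeletonize()] result.
#' @param length_window `c(min, max)` in um.
#' @return List with `segments` (complete segments with an `in_window`
#'   column), `l_c` (mean in-window length, um; `NA` if no segment
#'   qualifies), `n_segments_used`.
#' @export
segment_stats <- function(sk, length_window = c(1, 10)) {
  stopifnot(inherits(sk, "skeleton"))
  seg <- sk$segments
  complete <- seg[!seg$touches_border & !seg$closed, , drop = FALSE]
  complete$in_window <- complete$length_um >= length_window[1] &
    complete$length_um <= length_window[2]
  used <- complete$length_um[complete$in_window]
  if (length(used) == 0L) {
    message("segment_stats: no segments inside the length window; l_c missing")
    return(list(segments = complete, l_c = NA_real_, n_segments_used = 0L))
  }
  list(segments = complete, l_c = mean(used),
       n_segments_used = length(used))
}

#' Network density of a skeleton
#'
#' Total skeleton length connected to the network per unit area (um/um^2),
#' excluding dangling and free fiber ends: only branches whose both termini
#' are junctions, plus closed cycles, contribute. An isolated fiber with no
#' junctions therefore has density zero.
#'
#' @param sk a [skeletonize()] result.
#' @param analysis_area_um2 analysed frame area in um^2.
#' @return Network density `rho` in um/um^2.
#' @export
network_density <- function(sk, analysis_area_um2) {
  stopifnot(inherits(sk, "skeleton"))
  if (analysis_area_um2 <= 0)
    stop("network_density: analysis area must be positive", call. = FALSE)
  seg <- sk$segments
  core <- seg$closed | (seg$from_type == "junction" & seg$to_type == "junction")
  sum(seg$length_um[core]) / analysis_area_um2
}

#' Full microstructural descriptor extraction from one mask
#'
#' Convenience pipeline: skeletonize, sample radii, count crosslinks,
#' decompose segments, and measure porosity and pore statistics on a single
#' binary mask.
#'
#' @param mask a [binary_mask()].
#' @param length_window segment-length window for `l_c`, um.
#' @param exclusion_factor junction exclusion factor for radius sampling.
#' @param fit_fiber_types fit a Gaussian mixture to the radius samples
#'   (see [select_components()]) when enough samples exist.
#' @param k_max maximum number of mixture components scanned.
#' @param seed seed for the mixture fit.
#' @return Object of class `layer_descriptors`: list with `rho_b`, `rho`,
#'   `l_c`, `porosity`, `pore_summary`, `radii`, `fiber_model` (or `NULL`),
#'   `skeleton`, `n_segments_used`, `area_um2`.
#' @export
analyze_mask <- function(mask, length_window = c(1, 10), exclusion_factor = 2,
                         fit_fiber_types = TRUE, k_max = 6L, seed = 1L) {
  stopifnot(inherits(mask, "binary_mask"))
  area <- frame_area_um2(mask)
  sk <- skeletonize(mask)
  dm <- distance_map(mask)
  radii <- radius_samples(sk, dm, exclusion_factor)
  cl <- detect_crosslinks(sk, area)
  ss <- segment_stats(sk, length_window)
  rho <- network_density(sk, area)
  pores <- find_pores(mask)
  psum <- pore_statistics(pores)
  psum$porosity <- porosity(mask)
  model <- NULL
  if (fit_fiber_types && length(radii) >= 10 * 1) {
    model <- tryCatch(select_components(radii, k_max = k_max, seed = seed),
                      error = function(e) NULL)
  }
  structure(list(rho_b = cl$rho_b, rho = rho, l_c = ss$l_c,
                 porosity = psum$porosity, pore_summary = psum,
                 radii = radii, fiber_model = model, skeleton = sk,
                 n_segments_used = ss$n_segments_used, area_um2 = area),
            class = "layer_descriptors")
}

#' @export
print.layer_descriptors <- function(x, ...) {
  cat(sprintf(paste0("<layer_descriptors> rho_b = %.4f um^-2, rho = %.3f um/um^2, ",
                     "l_c = %s um, porosity = %.3f, %d radius samples\n"),
              x$rho_b, x$rho,
              if (is.na(x$l_c)) "NA" else sprintf("%.2f", x$l_c),
              x$porosity, length(x$radii)))
  if (!is.null(x$fiber_model))
    cat(sprintf("  fiber types: K = %d, means %s um\n", x$fiber_model$K,
                paste(sprintf("%.3f", x$fiber_model$mean), collapse = ", ")))
  invisible(x)
}
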