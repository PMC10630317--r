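#' Hertz forward model for spherical contact
#'
#' Force in uN for a rigid sphere of radius `R_um` indenting an elastic
#' half-space of reduced modulus `E_star_kpa` to depth `d_um` beyond the
#' contact point: `F = (4/3) E* sqrt(R) d^1.5`. This is the single place the
#' kPa -> uN/um^2 (MPa) unit conversion happens.
#'
#' @param d_um indentation depth in um (measured from the contact point).
#' @param E_star_kpa reduced modulus in kPa.
#' @param R_um indenter radius in um.
#' @return Force in uN (0 for non-positive depths).
#' @export
hertz_force <- function(d_um, E_star_kpa, R_um) {
  d <- pmax(d_um, 0)
  (4 / 3) * (E_star_kpa / .KPA_PER_MPA) * sqrt(R_um) * d^1.5
}

#' Specification of a synthetic micro-indentation experiment
#'
#' Encodes a displacement-controlled three-stage indentation: loading at
#' `load_rate`, a dwell at constant depth, and unloading at `unload_rate`,
#' matching the acquisition protocol of the emulated instrument (load
#' 3 um/s, 50 s dwell, unload 1 um/s, probe radius 92.03 um, maximum depth
#' ~65-75 um).
#'
#' @param E_sample elastic modulus of the sample, kPa.
#' @param poisson_ratio Poisson's ratio in `[0, 0.5)`.
#' @param R_indenter probe radius, um.
#' @param d_max maximum commanded depth, um.
#' @param load_rate,unload_rate stage rates, um/s.
#' @param dwell_time dwell duration, s.
#' @param contact_offset depth at which true contact occurs, um (surface
#'   standoff; force is zero before it).
#' @param noise_sd Gaussian force noise, uN.
#' @param popin_events list of `c(depth_um, force_drop_uN)` pairs inserted as
#'   step force drops on the loading stage (carried through dwell/unload, as
#'   for a non-recoverable network rearrangement).
#' @param sample_rate sampling frequency, Hz.
#' @param seed RNG seed.
#' @return Object of class `indentation_spec`.
#' @export
indentation_spec <- function(E_sample = 55.1, poisson_ratio = 0,
                             R_indenter = 92.03, d_max = 70,
                             load_rate = 3, dwell_time = 50, unload_rate = 1,
                             contact_offset = 0, noise_sd = 0.2,
                             popin_events = list(), sample_rate = 200,
                             seed = 1L) {
  if (E_sample <= 0) stop("indentation_spec: E_sample must be > 0", call. = FALSE)
  if (poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("indentation_spec: poisson_ratio must be in [0, 0.5)", call. = FALSE)
  if (d_max <= 0) stop("indentation_spec: d_max must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("indentation_spec: noise_sd must be >= 0", call. = FALSE)
  if (d_max <= contact_offset)
    stop("indentation_spec: d_max must exceed contact_offset", call. = FALSE)
  structure(list(E_sample = E_sample, poisson_ratio = poisson_ratio,
                 R_indenter = R_indenter, d_max = d_max,
                 load_rate = load_rate, dwell_time = dwell_time,
                 unload_rate = unload_rate, contact_offset = contact_offset,
                 noise_sd = noise_sd, popin_events = popin_events,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "indentation_spec")
}

#' Generate a synthetic force-indentation curve
#'
#' Simulates the three-stage depth program of an [indentation_spec()] and
#' evaluates the Hertz forward model (with the reduced modulus
#' `E* = E / (1 - nu^2)`) plus Gaussian force noise and optional pop-in force
#' drops. The true stage labels, pop-in event log and generating spec are
#' attached for recovery testing.
#'
#' @param spec an [indentation_spec()].
#' @return An `indentation_curve`: data frame with columns `time_s`,
#'   `depth_um`, `force_uN`, `stage`, plus metadata attributes (`metadata`,
#'   `true_stage`, `events`, `spec`).
#' @export
generate_indentation_curve <- function(spec) {
  stopifnot(inherits(spec, "indentation_spec"))
  set.seed(spec$seed)
  dt <- 1 / spec$sample_rate
  t_load <- spec$d_max / spec$load_rate
  t_unload <- spec$d_max / spec$unload_rate
  tt <- seq(0, t_load + spec$dwell_time + t_unload, by = dt)
  depth <- ifelse(tt <= t_load, tt * spec$load_rate,
           ifelse(tt <= t_load + spec$dwell_time, spec$d_max,
                  pmax(0, spec$d_max - (tt - t_load - spec$dwell_time) *
                         spec$unload_rate)))
  stage <- ifelse(tt <= t_load, "load",
           ifelse(tt <= t_load + spec$dwell_time, "dwell", "unload"))

  E_star <- spec$E_sample / (1 - spec$poisson_ratio^2)
  force <- hertz_force(depth - spec$contact_offset, E_star, spec$R_indenter)

  # pop-ins: permanent step drops triggered at given loading depths
  events <- NULL
  if (length(spec$popin_events)) {
    ev <- do.call(rbind, spec$popin_events)
    colnames(ev) <- c("depth_um", "drop_uN")
    events <- as.data.frame(ev)
    for (k in seq_len(nrow(events))) {
      hit <- stage == "load" & depth >= events$depth_um[k]
      first <- which(hit)[1]
      if (!is.na(first)) {
        drop_idx <- seq(first, length(force))
        force[drop_idx] <- pmax(0, force[drop_idx] - events$drop_uN[k])
      }
    }
  }
  if (spec$noise_sd > 0) force <- force + rnorm(length(force), 0, spec$noise_sd)

  curve <- data.frame(time_s = tt, depth_um = depth, force_uN = force,
                      stage = stage, stringsAsFactors = FALSE)
  structure(curve, class = c("indentation_curve", "data.frame"),
            metadata = list(R_indenter = spec$R_indenter, d_max = spec$d_max,
                            thickness_mm = 10, load_rate = spec$load_rate,
                            unload_rate = spec$unload_rate,
                            poisson_ratio = spec$poisson_ratio),
            true_stage = stage, events = events, spec = spec)
}

#' Write / read indentation curves as CSV
#'
#' The on-disk format is a plain CSV with header `time_s,depth_um,force_uN`;
#' stage labels are not stored (they are re-derived by [parse_curve()]).
#'
#' @param curve an `indentation_curve` (or any data frame with the three
#'   columns).
#' @param path destination path.
#' @export
write_curve_csv <- function(curve, path) {
  write.csv(curve[, c("time_s", "depth_um", "force_uN")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
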