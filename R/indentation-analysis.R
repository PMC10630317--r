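#' Parse a force-indentation record
#'
#' Reads a CSV with columns `time_s, depth_um, force_uN` (or accepts an
#' equivalent data frame) and labels the three stages of a
#' displacement-controlled indentation - load, dwell, unload - from the sign
#' of the smoothed depth rate with a hysteresis threshold. Stage order is
#' enforced (load, then dwell, then unload) and sub-threshold flicker runs
#' are absorbed into their predecessor.
#'
#' @param x path to a CSV file, or a data frame with the three columns.
#' @param metadata named list merged into the curve metadata
#'   (`R_indenter` um, `thickness_mm`, ...). When both `d_max` and
#'   `thickness_mm` are known the substrate-effect guard `d_max/t_f < 0.1`
#'   is checked and a warning raised if violated.
#' @param rate_threshold depth-rate magnitude (um/s) separating dwell from
#'   load/unload.
#' @return An `indentation_curve` data frame (`time_s, depth_um, force_uN,
#'   stage`) with a `metadata` attribute.
#' @export
parse_curve <- function(x, metadata = list(), rate_threshold = 0.1) {
  df <- if (is.character(x)) read.csv(x) else as.data.frame(x)
  need <- c("time_s", "depth_um", "force_uN")
  if (!all(need %in% names(df)))
    stop("parse_curve: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(diff(df$time_s) <= 0))
    stop("parse_curve: time must be strictly increasing", call. = FALSE)

  stage <- label_stages(df$time_s, df$depth_um, rate_threshold)
  df <- df[, need]
  df$stage <- stage

  md <- utils::modifyList(list(R_indenter = NA_real_,
                               d_max = max(df$depth_um),
                               thickness_mm = NA_real_), metadata)
  if (is.finite(md$d_max) && is.finite(md$thickness_mm)) {
    ratio <- md$d_max / (md$thickness_mm * 1000)
    if (ratio >= 0.1)
      warning(sprintf("parse_curve: d_max/t_f = %.3f >= 0.1; substrate effects likely",
                      ratio))
  }
  structure(df, class = c("indentation_curve", "data.frame"), metadata = md)
}

# Stage labelling by smoothed depth-rate sign with hysteresis, then run
# cleanup enforcing the load -> dwell -> unload order.
label_stages <- function(time_s, depth_um, rate_threshold) {
  n <- length(time_s)
  if (n < 3) return(rep("load", n))
  rate <- c(NA, diff(depth_um) / diff(time_s))
  rate[1] <- rate[2]
  k <- min(5L, n)
  rate <- as.numeric(stats::filter(rate, rep(1 / k, k), sides = 2))
  first <- which(!is.na(rate))[1]
  last <- max(which(!is.na(rate)))
  rate[seq_len(first - 1L)] <- rate[first]
  if (last < n) rate[(last + 1L):n] <- rate[last]
  lab <- ifelse(rate > rate_threshold, "load",
                ifelse(rate < -rate_threshold, "unload", "dwell"))
  # absorb runs shorter than 3 samples into the previous run
  r <- rle(lab)
  if (length(r$lengths) > 1) {
    for (i in seq(2, length(r$lengths))) {
      if (r$lengths[i] < 3) r$values[i] <- r$values[i - 1]
    }
    lab <- inverse.rle(r)
    r <- rle(lab)
  }
  # enforce monotone stage order
  order_rank <- c(load = 1, dwell = 2, unload = 3)
  rk <- order_rank[r$values]
  rk <- cummax(rk)
  r$values <- names(order_rank)[rk]
  inverse.rle(r)
}

#' Detect pop-in events on the loading stage
#'
#' Pop-ins are sudden force drops while depth still increases, indicating a
#' non-recoverable reorganisation of the fiber network under the probe. An
#' event is declared where the force decreases by more than
#' `max(3 * noise_sd, floor_uN)` between consecutive loading samples;
#' adjacent triggering samples are merged into one event.
#'
#' @param curve an `indentation_curve`.
#' @param floor_uN absolute drop floor in uN (default 1).
#' @param noise_sd noise level in uN; `NULL` estimates it robustly from the
#'   median absolute successive force difference on the loading stage.
#' @return Data frame `depth_um, drop_uN` (zero rows when no event).
#' @export
detect_pop_ins <- function(curve, floor_uN = 1, noise_sd = NULL) {
  ld <- curve[curve$stage == "load", , drop = FALSE]
  if (nrow(ld) < 3)
    stop("detect_pop_ins: loading stage missing or too short", call. = FALSE)
  if (is.null(noise_sd)) noise_sd <- mad(diff(ld$force_uN)) / sqrt(2)
  thr <- max(3 * noise_sd, floor_uN)
  # running median keeps step edges sharp while suppressing sample noise
  k <- min(5L, nrow(ld) - (1 - nrow(ld) %% 2))
  Fs <- if (nrow(ld) >= 5) as.numeric(stats::runmed(ld$force_uN, k)) else
    ld$force_uN
  dF <- diff(Fs)
  dd <- diff(ld$depth_um)
  hit <- which(dF < -thr & dd >= 0)
  if (length(hit) == 0L)
    return(data.frame(depth_um = numeric(0), drop_uN = numeric(0)))
  grp <- cumsum(c(1, diff(hit) > 1))
  out <- do.call(rbind, lapply(split(hit, grp), function(ix) {
    data.frame(depth_um = ld$depth_um[ix[1]],
               drop_uN = -(sum(dF[ix])))
  }))
  rownames(out) <- NULL
  out
}

#' Derivative of force with respect to depth on the loading stage
#'
#' Local second-order polynomial (sliding window in depth) estimate of
#' `dF/du` against `F`, the quantity whose power-law form `dF/du = K F^n`
#' makes the Hertz analysis independent of the contact point.
#'
#' @param curve an `indentation_curve`.
#' @param window_um full width of the sliding depth window, um.
#' @param depth_floor_um loading samples shallower than this are ignored
#'   (noise near first touch; the method needs no precise contact point, any
#'   value above the approach noise works).
#' @return Data frame `depth_um, force_uN, dFdu` for the loading stage.
#' @export
derivative_estimate <- function(curve, window_um = 2, depth_floor_um = 0) {
  ld <- curve[curve$stage == "load" & curve$depth_um >= depth_floor_um, ,
              drop = FALSE]
  if (nrow(ld) < 20)
    stop("derivative_estimate: need at least 20 loading samples, got ",
         nrow(ld), call. = FALSE)
  u <- ld$depth_um
  F <- ld$force_uN
  n <- length(u)
  half <- window_um / 2
  dFdu <- rep(NA_real_, n)
  lo <- 1L
  hi <- 1L
  for (i in seq_len(n)) {
    while (lo < n && u[lo] < u[i] - half) lo <- lo + 1L
    while (hi < n && u[hi + 1L] <= u[i] + half) hi <- hi + 1L
    ix <- lo:hi
    if (length(ix) < 5) next
    z <- u[ix] - u[i]  # centred for conditioning
    X <- cbind(1, z, z^2)
    cf <- tryCatch(solve(crossprod(X), crossprod(X, F[ix])),
                   error = function(e) NULL)
    if (!is.null(cf)) dFdu[i] <- cf[2]
  }
  ok <- !is.na(dFdu)
  data.frame(depth_um = u[ok], force_uN = F[ok], dFdu = dFdu[ok])
}

#' Power-law fit of the force derivative
#'
#' Least-squares fit of `log(dF/du)` against `log F` restricted to the force
#' window (default 5-30 uN), giving the prefactor `K` and exponent `n` of
#' `dF/du = K F^n`. Hertzian spherical contact implies `n = 1/3`.
#'
#' @param samples output of [derivative_estimate()].
#' @param window `c(F_min, F_max)` force window in uN.
#' @return List `K, n, n_points_used, residual_sd, window`.
#' @export
fit_power_law <- function(samples, window = c(5, 30)) {
  sel <- samples$force_uN >= window[1] & samples$force_uN <= window[2] &
    samples$dFdu > 0
  if (sum(sel) < 10)
    stop(sprintf("fit_power_law: only %d usable samples inside the [%g, %g] uN window (need >= 10)",
                 sum(sel), window[1], window[2]), call. = FALSE)
  lf <- log(samples$force_uN[sel])
  ld <- log(samples$dFdu[sel])
  fit <- lm(ld ~ lf)
  list(K = exp(coef(fit)[[1]]), n = coef(fit)[[2]],
       n_points_used = sum(sel),
       # suppressed: summary.lm warns on numerically perfect fits
       residual_sd = suppressWarnings(summary(fit)$sigma), window = window)
}

#' Elastic moduli from a derivative-form Hertz fit
#'
#' Inverts the Hertz derivative relation. With `F = (4/3) E* sqrt(R) d^1.5`
#' one has `dF/du = K F^(1/3)` where
#' `K = 2 (3/4)^(1/3) E*^(2/3) R^(1/3)`, hence `E* = K^(3/2) / sqrt(6 R)`.
#' `K` carries the mixed units of the uN/um fit; the result is converted to
#' kPa here. The fit is accepted only if the free exponent is close to the
#' Hertzian 1/3 (`|n - 1/3| <= n_tol`); otherwise no modulus is emitted.
#'
#' @param K,n power-law fit parameters from [fit_power_law()].
#' @param R_um indenter radius, um.
#' @param poisson_ratio Poisson's ratio used for `E = E* (1 - nu^2)` under a
#'   rigid probe. The tissue value is unknown; 0 is the transparent default
#'   and `E_star` is always reported alongside.
#' @param n_tol exponent acceptance tolerance (default 0.1).
#' @return List `E_star_kpa, E_kpa, n, accepted`; when rejected the moduli
#'   are `NA` and `reason` explains why.
#' @export
modulus_from_fit <- function(K, n, R_um, poisson_ratio = 0, n_tol = 0.1) {
  if (abs(n - 1 / 3) > n_tol) {
    return(list(E_star_kpa = NA_real_, E_kpa = NA_real_, n = n,
                accepted = FALSE,
                reason = sprintf("exponent n = %.3f deviates from 1/3 by more than %.2f",
                                 n, n_tol)))
  }
  E_star_mpa <- K^1.5 / sqrt(6 * R_um)
  E_star <- E_star_mpa * .KPA_PER_MPA
  list(E_star_kpa = E_star, E_kpa = E_star * (1 - poisson_ratio^2),
       n = n, accepted = TRUE, reason = NULL)
}

#' Full indentation analysis of one curve
#'
#' Pipeline: stage labelling (if absent), pop-in detection, derivative
#' estimation, power-law fit in the force window, and modulus extraction.
#' When pop-ins occur inside the fit window the window is truncated at the
#' first event (default) or the curve rejected.
#'
#' @param curve an `indentation_curve` (from [parse_curve()] or the
#'   generator).
#' @param R_um indenter radius, um; defaults to the curve metadata.
#' @param window force fit window, uN.
#' @param poisson_ratio Poisson's ratio.
#' @param popin_policy `"truncate"` (fit below the first pop-in) or
#'   `"reject"`.
#' @param ... passed to [derivative_estimate()].
#' @return Object of class `hertz_fit`: list with `K, n, E_star_kpa, E_kpa,
#'   accepted, reason, window, n_points_used, pop_ins`.
#' @export
analyze_indentation <- function(curve, R_um = NULL, window = c(5, 30),
                                poisson_ratio = 0,
                                popin_policy = c("truncate", "reject"), ...) {
  popin_policy <- match.arg(popin_policy)
  if (is.null(R_um)) {
    R_um <- attr(curve, "metadata")$R_indenter
    if (is.null(R_um) || !is.finite(R_um))
      stop("analyze_indentation: indenter radius unknown; pass R_um",
           call. = FALSE)
  }
  pops <- detect_pop_ins(curve)
  if (nrow(pops) > 0) {
    ld <- curve[curve$stage == "load", ]
    f_at_first <- ld$force_uN[which(ld$depth_um >= pops$depth_um[1])[1]]
    if (is.finite(f_at_first) && f_at_first < window[2]) {
      if (popin_policy == "reject")
        return(structure(list(K = NA, n = NA, E_star_kpa = NA, E_kpa = NA,
                              accepted = FALSE,
                              reason = "pop-in inside fit window (policy: reject)",
                              window = window, n_points_used = 0L,
                              pop_ins = pops),
                         class = "hertz_fit"))
      window[2] <- min(window[2], f_at_first)
    }
  }
  dv <- derivative_estimate(curve, ...)
  pl <- fit_power_law(dv, window)
  mod <- modulus_from_fit(pl$K, pl$n, R_um, poisson_ratio)
  structure(list(K = pl$K, n = pl$n, E_star_kpa = mod$E_star_kpa,
                 E_kpa = mod$E_kpa, accepted = mod$accepted,
                 reason = mod$reason, window = window,
                 n_points_used = pl$n_points_used, pop_ins = pops,
                 poisson_ratio = poisson_ratio, R_um = R_um),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  if (x$accepted)
    cat(sprintf("<hertz_fit> n = %.4f, K = %.4f, E* = %.1f kPa, E = %.1f kPa (window %g-%g uN, %d pts)\n",
                x$n, x$K, x$E_star_kpa, x$E_kpa, x$window[1], x$window[2],
                x$n_points_used))
  else
    cat(sprintf("<hertz_fit> rejected: %s\n", x$reason))
  if (nrow(x$pop_ins) > 0)
    cat(sprintf("  %d pop-in event(s), first at %.1f um\n",
                nrow(x$pop_ins), x$pop_ins$depth_um[1]))
  invisible(x)
}
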