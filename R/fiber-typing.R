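#' Fit a 1-D Gaussian mixture to fiber radius samples
#'
#' Expectation-maximisation fit of a `k`-component univariate Gaussian
#' mixture to the radius histogram, deconvolving the dominant hyphal fiber
#' types. Each component is a fiber type characterised by its mean radius,
#' spread and mixing weight. The model is scored with
#' `AIC = 2 p - 2 log L`, `p = 3k - 1` free parameters.
#'
#' A standard-deviation floor (default half the pixel size carried by the
#' samples) prevents components from collapsing onto the discretised radius
#' values.
#'
#' @param radii numeric vector of radii in um (a [radius_samples()] object
#'   or plain numeric). At least `10 * k` samples are required.
#' @param k number of components.
#' @param seed master seed; restarts use seeds derived from it, making the
#'   fit deterministic.
#' @param n_init number of EM restarts; the best log-likelihood wins.
#' @param sd_floor minimum component sd in um; `NULL` takes half the pixel
#'   size from the samples' attributes, falling back to 1e-4.
#' @param max_iter,tol EM stopping rule (relative log-likelihood change).
#' @return Object of class `fiber_type_model`: list with `K`, `mean`, `sd`,
#'   `weight` (sorted by mean), `log_likelihood`, `aic`, `n`, `seed`.
#' @export
fit_mixture <- function(radii, k, seed = 1L, n_init = 5L, sd_floor = NULL,
                        max_iter = 300L, tol = 1e-7) {
  x <- as.numeric(radii)
  n <- length(x)
  if (n < 10 * k)
    stop(sprintf("fit_mixture: %d samples given but at least %d (10 per component) required for k = %d",
                 n, 10 * k, k), call. = FALSE)
  if (is.null(sd_floor)) {
    ps <- attr(radii, "pixel_size")
    sd_floor <- if (!is.null(ps)) ps / 2 else 1e-4
  }
  if (sd(x) < .Machine$double.eps && k > 1)
    stop("fit_mixture: degenerate all-equal samples cannot support k > 1",
         call. = FALSE)

  best <- NULL
  for (init in seq_len(n_init)) {
    set.seed(seed + 7919L * init)
    fit <- em_gauss1d(x, k, sd_floor, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$mean)
  p <- 3 * k - 1
  structure(list(K = as.integer(k), mean = best$mean[ord], sd = best$sd[ord],
                 weight = best$weight[ord], log_likelihood = best$loglik,
                 aic = 2 * p - 2 * best$loglik, n = n, seed = as.integer(seed)),
            class = "fiber_type_model")
}

# One EM run with random-quantile initialisation (RNG state set by caller).
em_gauss1d <- function(x, k, sd_floor, max_iter, tol) {
  n <- length(x)
  mu <- sort(sample(x, k)) + rnorm(k, 0, sd(x) / 100 + sd_floor / 10)
  sg <- rep(max(sd(x) / k, sd_floor), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # E step in log space
    logd <- vapply(seq_len(k),
                   function(j) log(w[j]) + dnorm(x, mu[j], sg[j], log = TRUE),
                   numeric(n))
    m <- logd[, 1L]
    if (k > 1) for (j in 2:k) m <- pmax(m, logd[, j])
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    resp <- exp(logd - lse)
    # M step
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sg <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
    sg <- pmax(sg, sd_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(mean = mu, sd = sg, weight = w, loglik = ll)
}

#' @export
print.fiber_type_model <- function(x, ...) {
  cat(sprintf("<fiber_type_model> K = %d, logL = %.2f, AIC = %.2f (n = %d)\n",
              x$K, x$log_likelihood, x$aic, x$n))
  for (j in seq_len(x$K))
    cat(sprintf("  type %d: mean %.3f um, sd %.3f um, weight %.3f\n",
                j, x$mean[j], x$sd[j], x$weight[j]))
  invisible(x)
}

#' Select the number of fiber types by AIC
#'
#' Fits mixtures with `k = 1..k_max` components (each the best of `n_init`
#' EM restarts) and returns the fit minimising the Akaike information
#' criterion, which penalises extra components and so prevents overfitting
#' the radius histogram. All AIC values scanned are attached as the
#' `aic_path` attribute.
#'
#' @inheritParams fit_mixture
#' @param k_max largest component count scanned (default 6: dominant-type
#'   counts of 2-4 are typical, with headroom).
#' @return The AIC-minimising `fiber_type_model`.
#' @export
select_components <- function(radii, k_max = 6L, seed = 1L, n_init = 5L,
                              sd_floor = NULL) {
  if (k_max < 1) stop("select_components: k_max must be >= 1", call. = FALSE)
  n <- length(radii)
  ks <- seq_len(k_max)
  ks <- ks[10 * ks <= n]
  if (length(ks) == 0L)
    stop(sprintf("select_components: %d samples support no model (need >= 10)", n),
         call. = FALSE)
  fits <- lapply(ks, function(k)
    fit_mixture(radii, k, seed = seed + 1000L * k, n_init = n_init,
                sd_floor = sd_floor))
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  best <- fits[[which.min(aics)]]
  attr(best, "aic_path") <- data.frame(k = ks, aic = aics)
  best
}

#' Export a histogram with the fitted mixture density
#'
#' Emits a CSV with columns `bin_center, count, model_density` for plotting
#' radius histograms against their mixture fit.
#'
#' @param radii radius samples in um.
#' @param model a `fiber_type_model`.
#' @param path output CSV path.
#' @param bin_width histogram bin width in um.
#' @export
export_histogram <- function(radii, model, path, bin_width = 0.02) {
  x <- as.numeric(radii)
  breaks <- seq(0, max(x) + bin_width, by = bin_width)
  h <- hist(x, breaks = breaks, plot = FALSE)
  dens <- rowSums(vapply(seq_len(model$K), function(j)
    model$weight[j] * dnorm(h$mids, model$mean[j], model$sd[j]),
    numeric(length(h$mids))))
  write.csv(data.frame(bin_center = h$mids, count = h$counts,
                       model_density = dens),
            path, row.names = FALSE)
  invisible(path)
}
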