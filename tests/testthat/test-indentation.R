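test_that("parse_curve validates its input", {
  df <- data.frame(time_s = 1:5, depth_um = 1:5)
  expect_error(parse_curve(df), "columns")
  bad <- data.frame(time_s = c(1, 2, 2, 3), depth_um = 1:4, force_uN = 1:4)
  expect_error(parse_curve(bad), "strictly increasing")
})

test_that("stage labelling recovers the generator's stages within 2 samples", {
  sp <- indentation_spec(noise_sd = 0.2, seed = 21L, sample_rate = 50)
  cv <- generate_indentation_curve(sp)
  parsed <- parse_curve(cv[, c("time_s", "depth_um", "force_uN")])
  truth <- attr(cv, "true_stage")
  for (s in c("load", "dwell", "unload")) {
    expect_lte(abs(min(which(parsed$stage == s)) - min(which(truth == s))), 3)
    expect_lte(abs(max(which(parsed$stage == s)) - max(which(truth == s))), 3)
  }
  # recovered rates and dwell duration
  ld <- parsed[parsed$stage == "load", ]
  ul <- parsed[parsed$stage == "unload", ]
  dw <- parsed[parsed$stage == "dwell", ]
  expect_equal(diff(range(ld$depth_um)) / diff(range(ld$time_s)), 3,
               tolerance = 0.05)
  expect_equal(diff(range(ul$depth_um)) / diff(range(ul$time_s)), 1,
               tolerance = 0.05)
  expect_equal(diff(range(dw$time_s)), 50, tolerance = 1)
})

test_that("substrate-effect guard warns when d_max/t_f >= 0.1", {
  cv <- generate_indentation_curve(indentation_spec(seed = 2L, d_max = 70))
  expect_warning(parse_curve(cv[, 1:3], metadata = list(thickness_mm = 0.5)),
                 "substrate")
  expect_silent(parse_curve(cv[, 1:3], metadata = list(thickness_mm = 10)))
})

test_that("pop-in detection: clean curve silent, injected drops found, sub-floor ignored", {
  clean <- generate_indentation_curve(indentation_spec(noise_sd = 0, seed = 1L))
  expect_equal(nrow(detect_pop_ins(clean)), 0L)
  noisy <- generate_indentation_curve(indentation_spec(noise_sd = 0.3, seed = 5L))
  expect_equal(nrow(detect_pop_ins(noisy)), 0L)
  two <- generate_indentation_curve(
    indentation_spec(noise_sd = 0.2, popin_events = list(c(30, 5), c(50, 5)),
                     seed = 6L))
  ev <- detect_pop_ins(two)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$depth_um, c(30, 50), tolerance = 0.5)
  # a drop below the absolute floor is not an event
  small <- generate_indentation_curve(
    indentation_spec(noise_sd = 0, popin_events = list(c(30, 0.5)), seed = 7L))
  expect_equal(nrow(detect_pop_ins(small, floor_uN = 1)), 0L)
})

test_that("local-polynomial derivative is exact on a quadratic", {
  u <- seq(0, 1, by = 0.002)
  cv <- data.frame(time_s = u, depth_um = u, force_uN = u^2,
                   stage = "load")
  dv <- derivative_estimate(cv, window_um = 0.05)
  inner <- dv$depth_um > 0.05 & dv$depth_um < 0.95
  expect_lt(max(abs(dv$dFdu[inner] - 2 * dv$depth_um[inner])), 1e-6)
})

test_that("derivative of a noise-free Hertz curve is a 1/3 power law", {
  cv <- generate_indentation_curve(indentation_spec(noise_sd = 0, seed = 3L))
  dv <- derivative_estimate(cv)
  pl <- fit_power_law(dv, c(5, 30))
  expect_lt(abs(pl$n - 1 / 3), 1e-3)
})

test_that("power-law fit is exact on exact samples", {
  Fv <- seq(5, 30, length.out = 50)
  samples <- data.frame(depth_um = NA, force_uN = Fv, dFdu = 2 * Fv^0.5)
  pl <- fit_power_law(samples, c(5, 30))
  expect_equal(pl$K, 2, tolerance = 1e-12)
  expect_equal(pl$n, 0.5, tolerance = 1e-12)
  expect_error(fit_power_law(samples[1:3, ], c(5, 30)), "usable samples")
})

test_that("modulus inversion reproduces the forward oracle over an E* grid", {
  for (E in c(10, 55.1, 100)) {
    cv <- generate_indentation_curve(
      indentation_spec(E_sample = E, noise_sd = 0, seed = 4L))
    fit <- analyze_indentation(cv)
    expect_true(fit$accepted)
    expect_equal(fit$E_star_kpa, E, tolerance = 0.02, info = paste("E* =", E))
    expect_equal(abs(fit$n - 1 / 3) <= 0.1, TRUE)
  }
})

test_that("Poisson ratio propagates: E = E* at nu = 0, reduced otherwise", {
  mod0 <- modulus_from_fit(K = 1.2, n = 1 / 3, R_um = 92.03, poisson_ratio = 0)
  expect_equal(mod0$E_kpa, mod0$E_star_kpa)
  mod3 <- modulus_from_fit(K = 1.2, n = 1 / 3, R_um = 92.03, poisson_ratio = 0.3)
  expect_equal(mod3$E_kpa, mod3$E_star_kpa * (1 - 0.09))
  # exponent gate
  bad <- modulus_from_fit(K = 1.2, n = 0.6, R_um = 92.03)
  expect_false(bad$accepted)
  expect_true(is.na(bad$E_kpa))
  expect_match(bad$reason, "deviates")
})

test_that("recovery is independent of the contact offset (noise-free, 2%)", {
  for (off in c(0, 2.5, 5)) {
    cv <- generate_indentation_curve(
      indentation_spec(noise_sd = 0, contact_offset = off, seed = 8L))
    fit <- analyze_indentation(cv)
    expect_equal(fit$E_kpa, 55.1, tolerance = 0.02, info = paste("offset", off))
    expect_lt(abs(fit$n - 1 / 3), 1e-3)
  }
})

test_that("doubling R at fixed E* scales K by 2^(1/3)", {
  k_of <- function(R) {
    cv <- generate_indentation_curve(
      indentation_spec(noise_sd = 0, R_indenter = R, seed = 9L))
    analyze_indentation(cv, R_um = R)$K
  }
  expect_equal(k_of(2 * 92.03) / k_of(92.03), 2^(1 / 3), tolerance = 0.005)
})

test_that("pop-ins inside the window truncate it (or reject under policy)", {
  sp <- indentation_spec(noise_sd = 0.2, popin_events = list(c(8, 6)),
                         seed = 10L)
  cv <- generate_indentation_curve(sp)
  fit <- analyze_indentation(cv)  # default truncate
  expect_lt(fit$window[2], 30)
  rej <- analyze_indentation(cv, popin_policy = "reject")
  expect_false(rej$accepted)
  expect_match(rej$reason, "pop-in")
})
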