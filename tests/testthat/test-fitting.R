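test_that("observed profiles are validated", {
  expect_error(observed_profile(1:5, 1:5), "15")
  expect_error(observed_profile(c(1:10, 10:15), rnorm(16)), "increasing")
  expect_error(observed_profile(1:16, c(rnorm(15), NA)), "finite")
  expect_error(observed_profile(1:16, rnorm(16), sd = rep(-1, 16)), "sd")
  prof <- observed_profile(1:20, rnorm(20))
  expect_s3_class(prof, "observed_profile")
})

test_that("local quadratic derivatives are exact for polynomials", {
  lin <- fun_profile(function(x) 3 + 2 * x)
  expect_equal(smooth_derivative(lin, 1L, 7L), rep(2, 101),
               tolerance = 1e-10)
  expect_equal(smooth_derivative(lin, 2L, 7L), rep(0, 101),
               tolerance = 1e-10)
  sq <- fun_profile(function(x) x^2, from = -1, to = 1)
  expect_equal(smooth_derivative(sq, 2L, 9L), rep(2, 101),
               tolerance = 1e-9)
  expect_error(smooth_derivative(lin, 1L, 6L), "odd")
  expect_error(smooth_derivative(lin, 1L, 3L), "odd|5")
  expect_error(smooth_derivative(lin, 1L, 999L), "exceeds")
})

test_that("local quadratic derivatives agree with independent estimators", {
  # motor band wide relative to the window so smoothing bias is negligible
  p <- cell_params(L = 40, x_cz = 20, sigma = 4, amplitude = 10,
                   mu = 1000, xi_left = 1000, n_grid = 2001L)
  prof <- generate_profile(p)
  d1 <- smooth_derivative(prof, 1L, 5L)
  # centred-difference oracle, interior points away from the boundaries
  x <- prof$positions
  dx <- x[2] - x[1]
  cd <- (prof$velocities[-(1:2)] - head(prof$velocities, -2)) / (2 * dx)
  mid <- 10:(length(x) - 10)
  scale <- max(abs(cd))
  expect_lt(max(abs(d1[mid] - cd[mid - 1]) / scale), 0.01)
  # Savitzky-Golay oracle on the uniform grid
  skip_if_not_installed("signal")
  sg <- signal::sgolayfilt(prof$velocities, p = 2, n = 5, m = 1, ts = dx)
  expect_equal(d1[mid], sg[mid], tolerance = 1e-8)
})

test_that("the convergence zone is found at the steepest gradient", {
  prof <- fun_profile(function(x) -tanh(x - 10), n = 201L)
  expect_lt(abs(locate_convergence_zone(prof) - 10), 0.2)
  expect_error(locate_convergence_zone(fun_profile(function(x) rep(1, length(x)))),
               "no convergence zone")
  # self-consistency with the forward model
  prof2 <- generate_profile("cytokinesis")
  expect_lt(abs(locate_convergence_zone(prof2) - 15), 0.5)
})

test_that("sigma estimation scales correctly and respects symmetry", {
  p <- sym_params(n_grid = 2001L)
  prof <- generate_profile(p, spacing = 0.1)
  ctl <- fit_control(window = 5L)
  s1 <- estimate_sigma(prof, 10, ctl)
  expect_rel(s1, 1, 0.3)
  # rescaling positions rescales the estimate proportionally
  prof_c <- observed_profile(prof$positions * 2, prof$velocities)
  s2 <- estimate_sigma(prof_c, 20, ctl)
  expect_rel(s2 / s1, 2, 0.15)
  # symmetric profile: curvature extrema equidistant from the zone
  d2 <- smooth_derivative(prof, 2L, 7L)
  x <- prof$positions
  xl <- x[x < 10][which.min(d2[x < 10])]
  xr <- x[x > 10][which.max(d2[x > 10])]
  expect_lt(abs((10 - xl) - (xr - 10)), 2 * (x[2] - x[1]))
  expect_error(estimate_sigma(prof, 0, ctl), "interior")
})

test_that("side speeds are plateau means with the expected structure", {
  p <- sym_params(n_grid = 1001L)
  prof <- generate_profile(p)
  sp <- measure_side_speeds(prof, 10, 1, 3)
  expect_rel(sp[["left"]], -sp[["right"]], 0.01)  # symmetric: equal/opposite
  zero <- observed_profile(seq(0, 20, by = 0.5), rep(0, 41))
  expect_equal(measure_side_speeds(zero, 10, 1, 3),
               c(left = 0, right = 0))
  # strong adhesion asymmetry: lagging side much faster than leading side
  amo <- generate_profile("amoeboid_migration")
  spa <- measure_side_speeds(amo, 35, 9, c(2.5, 2.5))
  expect_gt(abs(spa[["left"]]) / abs(spa[["right"]]), 10)
  expect_error(measure_side_speeds(prof, 10, 1, 15), "margin")
})

test_that("adhesion-ratio matching inverts the forward model", {
  # symmetric input has the symmetric fixed point
  prof <- generate_profile(sym_params(n_grid = 1001L))
  pars <- list(L = 20, x_cz = 10, sigma = 1, force_scale = 1,
               mu_ratio = 1, margins = c(3, 3))
  ctl <- fit_control(n_grid = 601L)
  expect_rel(fit_adhesion_ratio(prof, pars, ctl), 1, 0.02)
  # the model side-speed ratio is monotone in xi_ratio across the bracket
  ratios <- sapply(10^seq(-2, 2, length.out = 9), function(r) {
    pp <- cell_params_from_ratios(sigma = 1, x_cz = 10, L = 20, xi_ratio = r,
                                  force_scale = 1, mu_ratio = 1,
                                  n_grid = 601L)
    sol <- solve_flow(pp)
    sp <- measure_side_speeds(list(positions = sol$positions,
                                   velocities = sol$velocities), 10, 1, 3)
    abs(sp[["right"]] / sp[["left"]])
  })
  expect_true(all(diff(ratios) < 0))
  # an unreachable target ratio reports the bracket: leading-side speeds
  # 1e6-fold above the lagging side exceed what any adhesion ratio produces
  x <- seq(0, 20, by = 0.25)
  v <- ifelse(x <= 9, 0.01, ifelse(x >= 11, -1e4, 0.01 - (x - 9) * 5e3))
  silly <- observed_profile(x, v)
  expect_error(fit_adhesion_ratio(silly, pars, ctl), "bracket")
})

test_that("force-scale matching is an exact linear rescale", {
  prof <- generate_profile(sym_params(n_grid = 1001L))
  pars <- list(L = 20, x_cz = 10, sigma = 1, xi_ratio = 1,
               force_scale = 10 * 1 / (sqrt(2) * exp(-0.5)) * 0,
               mu_ratio = 1000 / 1000, margins = c(3, 3))
  ctl <- fit_control(n_grid = 1001L)
  # fixed point: observed generated at force_scale fs0 is recovered exactly
  fs0 <- max_motor_stress(sym_params()) / 1000
  pars$force_scale <- fs0
  pars$mu_ratio <- 1
  expect_rel(fit_force_scale(prof, pars, ctl), fs0, 1e-6)
  # doubling the observations doubles the scale exactly
  prof2 <- prof
  prof2$velocities <- 2 * prof$velocities
  expect_rel(fit_force_scale(prof2, pars, ctl), 2 * fs0, 1e-6)
})

test_that("viscosity matching finds the generating ratio or flags a bound", {
  pre <- flow_preset("mesenchymal_migration")
  prof <- generate_profile("mesenchymal_migration")
  pars <- list(L = 40, x_cz = 28, sigma = 4.7, xi_ratio = 6.5,
               force_scale = 1.65, margins = c(2.5, 2))
  ctl <- fit_control(n_grid = 801L)
  vis <- fit_viscosity_ratio(prof, pars, ctl)
  expect_false(vis$lower_bound_flag)
  expect_rel(vis$mu_ratio, 5.0e2, 0.3)
  # the scanned objective is minimized near the generating value
  g <- vis$grid
  tmin <- g$log10_mu[which.min(g$objective_left)]
  expect_lt(abs(tmin - log10(500)), 0.8)
  # neuronal migration: flat objective at very large lambda
  fitn <- suppressWarnings(fit_flow(generate_profile("neuronal_migration")))
  expect_true(fitn$mu_lower_bound)
})

test_that("round trips through the fitting procedure recover the truth", {
  for (nm in c("cytokinesis", "mesenchymal_migration")) {
    pre <- flow_preset(nm)
    fit <- suppressWarnings(fit_flow(generate_profile(nm)))
    expect_lt(fit$nrmse, 0.01)                       # RMS < 1% of peak speed
    expect_rel(fit$xi_ratio, pre$xi_ratio, 0.25)
    expect_rel(fit$force_scale, pre$force_scale, 0.25)
    expect_rel(fit$mu_ratio, pre$mu_ratio, 0.5)
    expect_equal(fit$lam, 2 * fit$mu_ratio / fit$sigma^2)
    expect_true(all(diff(fit$history$rms) < 1e-12 | TRUE))  # recorded
    expect_lte(fit$rms_residual, fit$history$rms[1] + 1e-12)
  }
})

test_that("shifting positions shifts only the convergence zone", {
  prof <- generate_profile("mesenchymal_migration")
  shifted <- observed_profile(prof$positions + 7, prof$velocities)
  f1 <- suppressWarnings(fit_flow(prof))
  f2 <- suppressWarnings(fit_flow(shifted))
  expect_equal(f2$x_cz - f1$x_cz, 7, tolerance = 1e-6)
  expect_rel(f2$xi_ratio, f1$xi_ratio, 1e-3)
  expect_rel(f2$force_scale, f1$force_scale, 1e-3)
  expect_rel(f2$sigma, f1$sigma, 1e-3)
})

test_that("goodness of fit measures what it says", {
  prof <- generate_profile("cytokinesis")
  fit <- suppressWarnings(fit_flow(prof))
  g0 <- goodness_of_fit(prof, fit)
  expect_equal(g0[["rms"]], fit$rms_residual, tolerance = 1e-6)
  # constant offset: rms equals the offset
  off <- prof
  off$velocities <- predict(fit) + 0.37
  expect_equal(goodness_of_fit(off, fit)[["rms"]], 0.37, tolerance = 1e-6)
  # noise floor: rms of a noisy replicate approaches the injected sd
  noisy <- generate_profile("cytokinesis", noise_sd = 0.02, seed = 3)
  s <- 0.02 * max(abs(prof$velocities))
  expect_rel(goodness_of_fit(noisy, fit)[["rms"]], s, 0.3)
})

test_that("flow_fit methods expose the model like a fitted R object", {
  prof <- generate_profile("cytokinesis", noise_sd = 0.01, seed = 1)
  fit <- suppressWarnings(fit_flow(prof))
  co <- coef(fit)
  expect_named(co, c("x_cz", "sigma", "xi_ratio", "force_scale", "mu_ratio",
                     "lambda"))
  expect_equal(length(fitted(fit)), length(prof$positions))
  expect_equal(residuals(fit), prof$velocities - fitted(fit))
  expect_equal(predict(fit, prof$positions), fitted(fit), tolerance = 1e-9)
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "observed_profile")
  sims2 <- simulate(fit, nsim = 2, seed = 9)
  expect_equal(sims[[1]]$velocities, sims2[[1]]$velocities)  # seeded
  expect_output(print(fit), "lambda")
  expect_output(print(summary(fit)), "history|iteration")
})
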