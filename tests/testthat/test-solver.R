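test_that("adhesion profile follows the step and sigmoid conventions", {
  p <- cell_params(L = 20, x_cz = 10, sigma = 1, amplitude = 10,
                   mu = 100, xi_left = 2, xi_right = 8)
  x <- seq(0, 20, by = 0.5)
  xi <- build_adhesion_profile(p, x)
  expect_equal(xi[x < 10], rep(2, sum(x < 10)))
  expect_equal(xi[x >= 10], rep(8, sum(x >= 10)))   # right-closed at the CZ
  pc <- cell_params(L = 20, x_cz = 10, sigma = 1, amplitude = 10,
                    mu = 100, xi_left = 5)
  expect_equal(build_adhesion_profile(pc, x), rep(5, length(x)))
  ps <- cell_params(L = 20, x_cz = 10, sigma = 1, amplitude = 10,
                    mu = 100, xi_left = 2, xi_right = 8, smooth_width = 1)
  xis <- build_adhesion_profile(ps, x)
  expect_equal(xis[x == 10], 5)                     # sigmoid midpoint
  expect_true(all(diff(xis) >= 0))                  # monotone blend
})

test_that("solver respects linearity, scale invariance and zero forcing", {
  p0 <- sym_params()
  p0$amplitude <- 0
  expect_equal(solve_flow(p0)$velocities, rep(0, p0$n_grid))
  p1 <- sym_params()
  p2 <- sym_params()
  p2$amplitude <- 20
  expect_equal(solve_flow(p2)$velocities, 2 * solve_flow(p1)$velocities,
               tolerance = 1e-13)
  # joint rescale of xi, mu, amplitude leaves the flow unchanged
  p3 <- cell_params(L = 20, x_cz = 10, sigma = 1, amplitude = 10 * 37,
                    mu = 1000 * 37, xi_left = 1000 * 37,
                    xi_right = 3000 * 37, n_grid = 801)
  p4 <- cell_params(L = 20, x_cz = 10, sigma = 1, amplitude = 10,
                    mu = 1000, xi_left = 1000, xi_right = 3000, n_grid = 801)
  expect_equal(solve_flow(p3)$velocities, solve_flow(p4)$velocities,
               tolerance = 1e-12)
})

test_that("symmetric cells flow toward the zone but go nowhere", {
  p <- sym_params(n_grid = 1001L)
  sol <- solve_flow(p)
  v <- sol$velocities
  vmax <- max(abs(v))
  expect_lt(max(abs(v + rev(v))), 1e-10 * vmax)       # v(x) = -v(L - x)
  expect_lt(abs(v[(p$n_grid + 1) / 2]), 1e-10 * vmax) # v(L/2) = 0
  s <- flow_summary(sol)
  expect_lt(abs(s$com_velocity), 1e-8 * vmax)
  sd <- stress_decomposition(sol)
  expect_lt(abs(s$net_traction), 1e-6 * sum(abs(sd$traction)) *
              (p$L / p$n_grid))
  # traction antisymmetric about the zone
  expect_lt(max(abs(sd$traction + rev(sd$traction))),
            1e-10 * max(abs(sd$traction)))
})

test_that("the discrete force balance closes pointwise", {
  for (xi_r in c(1000, 50)) {
    p <- cell_params(L = 20, x_cz = 10, sigma = 1, amplitude = 10,
                     mu = 1000, xi_left = 1000, xi_right = xi_r,
                     n_grid = 2001)
    sd <- stress_decomposition(solve_flow(p))
    expect_lt(max(abs(sd$residual)), 1e-6 * max(abs(sd$motor)))
  }
  # integrated balance: net traction vanishes when the motor band decays
  # inside the domain (Neumann ends kill the viscous boundary terms); exact
  # by cancellation for symmetric adhesion, O(grid) otherwise
  psym <- cell_params(L = 20, x_cz = 10, sigma = 1, amplitude = 10,
                      mu = 1000, xi_left = 1000, n_grid = 2001)
  sds <- stress_decomposition(solve_flow(psym))
  dx <- diff(sds$position[1:2])
  expect_lt(abs(sum(sds$traction) * dx), 1e-6 * sum(abs(sds$traction)) * dx)
  net_rel <- function(n) {
    pa <- cell_params(L = 20, x_cz = 10, sigma = 1, amplitude = 10,
                      mu = 1000, xi_left = 1000, xi_right = 50, n_grid = n)
    sda <- stress_decomposition(solve_flow(pa))
    abs(sum(sda$traction)) / sum(abs(sda$traction))
  }
  expect_lt(net_rel(2001L), 2e-4)
  expect_gt(net_rel(2001L) / net_rel(4001L), 1.5)   # vanishes on refinement
  # grid mismatch is an error
  p <- sym_params()
  other <- sym_params(n_grid = 901L)
  expect_error(stress_decomposition(solve_flow(p), other), "grid")
})

test_that("flow decays from the zone with the dissipation length", {
  # narrow forcing in a long uniform-adhesion cell: log-slope of |v| over
  # [x_cz + 3 sigma, + 2 ell] should be -1/ell within 5%
  p <- cell_params(L = 40, x_cz = 20, sigma = 0.5, amplitude = 10,
                   mu = 4000, xi_left = 1000, n_grid = 4001)
  ell <- dissipation_length(p$mu, p$xi_left)
  sol <- solve_flow(p)
  lo <- p$x_cz + 3 * p$sigma
  sel <- sol$positions >= lo & sol$positions <= lo + 2 * ell
  slope <- stats::coef(stats::lm(log(abs(sol$velocities[sel])) ~
                                   sol$positions[sel]))[[2]]
  expect_rel(-1 / slope, ell, 0.05)
})

test_that("numerical stress partition at the peak follows lambda", {
  # symmetric reference domain; the analytic estimate is built on the
  # three-point stencil with spacing sigma/sqrt(2), so the numerical viscous
  # stress is evaluated with that same defining stencil
  for (lam in c(0.2, 2, 20, 200, 2000)) {
    xi <- 1000
    p <- cell_params(L = 40, x_cz = 20, sigma = 1, amplitude = 10,
                     mu = lam * xi / 2, xi_left = xi, n_grid = 2001)
    sol <- solve_flow(p)
    vat <- function(q) stats::approx(sol$positions, sol$velocities, q)$y
    xc <- peak_stress_locations(p)[["left"]]
    h <- p$sigma / sqrt(2)
    fv <- abs(p$mu * (vat(xc + h) - 2 * vat(xc) + vat(xc - h)) / h^2)
    tr <- abs(xi * vat(xc))
    fmax <- max_motor_stress(p)
    part <- stress_partition(fmax, lam)
    expect_lt(abs(fv - part[["viscous"]]),
              max(0.25 * part[["viscous"]], 0.05 * fmax))
    expect_lt(abs(tr - part[["traction"]]),
              max(0.25 * part[["traction"]], 0.05 * fmax))
  }
})

test_that("lambda sets the shape of the velocity profile", {
  # small lambda: flow localized within a few dissipation lengths of the CZ
  p2 <- sym_params(n_grid = 2001L)                  # lambda = 2, ell = 1
  sol2 <- solve_flow(p2)
  ell <- dissipation_length(p2$mu, p2$xi_left)
  left <- sol2$positions < p2$x_cz
  peak_left <- max(sol2$velocities[left])
  v5 <- stats::approx(sol2$positions, sol2$velocities,
                      p2$x_cz - 5 * ell)$y
  expect_lt(abs(v5), 0.15 * peak_left)
  # large lambda: near-uniform flow toward the zone on each side
  p200 <- sym_params(n_grid = 2001L, xi = 10)       # lambda = 200
  sol200 <- solve_flow(p200)
  sel <- sol200$positions <= p200$x_cz - 3 * p200$sigma
  vleft <- sol200$velocities[sel]
  expect_lt(stats::sd(vleft) / abs(mean(vleft)), 0.10)
})

test_that("grid refinement converges at second order", {
  p <- sym_params(n_grid = 2001L)
  r1 <- refine_check(p)
  expect_lt(r1$report, 1e-4)
  pd <- sym_params(n_grid = 4001L)
  r2 <- refine_check(pd)
  expect_gt(r1$report / r2$report, 3)   # ~4x per doubling for O(dx^2)
  expect_lt(r1$report / r2$report, 5.5)
  p0 <- sym_params()
  p0$amplitude <- 0
  expect_equal(refine_check(p0)$report, 0)
})

test_that("flow summary reports plateaus consistent with zero net traction", {
  p0 <- sym_params()
  p0$amplitude <- 0
  s0 <- flow_summary(solve_flow(p0))
  expect_equal(unlist(unclass(s0)), setNames(rep(0, 7), names(unclass(s0))))
  # strongly viscous asymmetric cell: plateau ratio from the traction balance
  lam <- 1e4
  xi_ratio <- 4
  p <- cell_params(L = 20, x_cz = 10, sigma = 0.5, amplitude = 10,
                   mu = lam * 0.5^2 / 2, xi_left = 1, xi_right = xi_ratio,
                   n_grid = 2001)
  s <- flow_summary(solve_flow(p))
  expected <- xi_ratio * (p$L - p$x_cz) / (1 * p$x_cz)
  expect_rel(s$plateau_left / (-s$plateau_right), expected, 0.1)
})

test_that("a coarse grid triggers a warning but still solves", {
  p <- cell_params(L = 20, x_cz = 10, sigma = 0.1, amplitude = 10,
                   mu = 1000, xi_left = 1000, n_grid = 101)
  expect_warning(sol <- solve_flow(p), "coarse")
  expect_true(all(is.finite(sol$velocities)))
})
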