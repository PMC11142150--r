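# Thomas algorithm for a tridiagonal system. The flow operator is strictly
# diagonally dominant (|diag| = |2a| + xi > |2a|), so no pivoting is needed.
thomas_solve <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  cp <- numeric(n - 1L)
  dp <- numeric(n)
  cp[1L] <- upper[1L] / diag[1L]
  dp[1L] <- rhs[1L] / diag[1L]
  for (i in 2:n) {
    m <- diag[i] - lower[i - 1L] * cp[i - 1L]
    if (i < n) cp[i] <- upper[i] / m
    dp[i] <- (rhs[i] - lower[i - 1L] * dp[i - 1L]) / m
  }
  v <- numeric(n)
  v[n] <- dp[n]
  for (i in (n - 1L):1L) v[i] <- dp[i] - cp[i] * v[i + 1L]
  v
}

#' Spatial adhesion profile
#'
#' Evaluates the adhesion coefficient on a position grid. With
#' `smooth_width = 0` the profile is a sharp step: `xi_left` for
#' `x < x_cz` and `xi_right` for `x >= x_cz` (the convergence-zone node takes
#' the right-hand value). With `smooth_width > 0` the step is replaced by a
#' monotone logistic blend centred at `x_cz` with that half-width, taking the
#' midpoint value `(xi_left + xi_right)/2` at `x_cz`.
#'
#' @param params a [cell_params()] object.
#' @param positions numeric vector of positions (µm).
#' @return Adhesion coefficient at each position.
#' @export
build_adhesion_profile <- function(params, positions) {
  validate_cell_params(params)
  if (params$smooth_width == 0) {
    ifelse(positions < params$x_cz, params$xi_left, params$xi_right)
  } else {
    w <- stats::plogis((positions - params$x_cz) / (params$smooth_width / 2))
    params$xi_left + (params$xi_right - params$xi_left) * w
  }
}

#' Solve the steady-state force balance for the flow profile
#'
#' Solves `F_m(x) + mu * v''(x) - xi(x) * v(x) = 0` on the uniform grid of
#' `params` with no-gradient (Neumann) boundary conditions `v'(0) = v'(L) = 0`
#' ("velocity is uniform at the cell edges"). Discretization is by centred
#' second-order differences with ghost points at the boundaries, giving a
#' tridiagonal linear system solved directly; the system is scaled by
#' `xi_left` before assembly so matrix entries stay in a moderate dynamic
#' range even at extreme viscosity/adhesion ratios.
#'
#' The equation is linear in `v`, so the solution scales proportionally with
#' the motor amplitude and is invariant under joint rescaling of
#' (`amplitude`, `mu`, `xi_left`, `xi_right`).
#'
#' @param params a [cell_params()] object.
#' @return An object of class `flow_profile`: a list with `positions`,
#'   `velocities` (lab frame, positive toward the leading edge), the
#'   generating `params` and a `params_id` string.
#' @examples
#' p <- cell_params(L = 20, x_cz = 10, sigma = 1, amplitude = 10,
#'                  mu = 1000, xi_left = 1000, n_grid = 801)
#' v <- solve_flow(p)
#' flow_summary(v)
#' @export
solve_flow <- function(params) {
  validate_cell_params(params)
  x <- grid_positions(params)
  dx <- x[2L] - x[1L]
  if (params$sigma < 10 * dx)
    warning("grid may be too coarse for the motor width: sigma = ",
            signif(params$sigma, 4), " < 10 * dx = ", signif(10 * dx, 4),
            call. = FALSE)
  s <- params$xi_left
  xi <- build_adhesion_profile(params, x) / s
  fm <- motor_stress(params, x) / s
  a <- (params$mu / s) / dx^2
  n <- params$n_grid
  dg <- -(2 * a + xi)
  lo <- rep(a, n - 1L)
  up <- rep(a, n - 1L)
  up[1L] <- 2 * a        # ghost point: v_0 = v_2
  lo[n - 1L] <- 2 * a    # ghost point: v_{n+1} = v_{n-1}
  v <- thomas_solve(lo, dg, up, -fm)
  structure(list(positions = x, velocities = v, params = params,
                 params_id = params_id(params)),
            class = "flow_profile")
}

#' @export
print.flow_profile <- function(x, ...) {
  cat(sprintf("flow profile: %d points on [0, %g] um\n",
              length(x$positions), max(x$positions)))
  cat(sprintf("  v range [%.4g, %.4g] %s; peak retrograde %.4g\n",
              min(x$velocities), max(x$velocities),
              x$params$velocity_unit, min(x$velocities)))
  invisible(x)
}

#' @export
as.data.frame.flow_profile <- function(x, ...) {
  data.frame(position = x$positions, velocity = x$velocities)
}

#' @export
plot.flow_profile <- function(x, ...) {
  graphics::plot(x$positions, x$velocities, type = "l", lwd = 2, col = "red3",
                 xlab = "position (um)",
                 ylab = paste0("velocity (", x$params$velocity_unit, ")"), ...)
  graphics::abline(h = 0, col = "grey70", lty = 2)
  graphics::abline(v = x$params$x_cz, col = "grey50", lty = 3)
  invisible(x)
}

# second derivative on the solver grid, ghost-point Neumann ends
second_difference <- function(v, dx) {
  n <- length(v)
  vpp <- numeric(n)
  vpp[2:(n - 1L)] <- (v[3:n] - 2 * v[2:(n - 1L)] + v[1:(n - 2L)]) / dx^2
  vpp[1L] <- 2 * (v[2L] - v[1L]) / dx^2
  vpp[n] <- 2 * (v[n - 1L] - v[n]) / dx^2
  vpp
}

#' Pointwise decomposition of the force balance
#'
#' Recomputes the three stresses of the model on the profile grid: motor
#' stress `F_m(x)`, viscous stress `mu * v''(x)` (centred differences, with
#' the same ghost-point treatment as the solver at the Neumann boundaries)
#' and substrate traction `T(x) = xi(x) * v(x)`, together with the residual
#' `F_m + F_visc - T`, which is at round-off level for a solver-produced
#' profile.
#'
#' @param profile a `flow_profile` from [solve_flow()].
#' @param params parameters on whose grid the profile was generated; defaults
#'   to the ones stored in the profile. A mismatch is an error.
#' @return Object of class `stress_decomposition`: a data frame with columns
#'   `position`, `motor`, `viscous`, `traction`, `residual` (plus the
#'   parameters as an attribute).
#' @export
stress_decomposition <- function(profile, params = profile$params) {
  stopifnot(inherits(profile, "flow_profile"))
  validate_cell_params(params)
  if (!identical(params_id(params), profile$params_id))
    stop("profile was not generated on this parameter grid", call. = FALSE)
  x <- profile$positions
  v <- profile$velocities
  dx <- x[2L] - x[1L]
  motor <- motor_stress(params, x)
  viscous <- params$mu * second_difference(v, dx)
  traction <- build_adhesion_profile(params, x) * v
  out <- data.frame(position = x, motor = motor, viscous = viscous,
                    traction = traction,
                    residual = motor + viscous - traction)
  attr(out, "params") <- params
  class(out) <- c("stress_decomposition", "data.frame")
  out
}

#' @export
plot.stress_decomposition <- function(x, ...) {
  graphics::matplot(x$position, cbind(x$motor, x$viscous, x$traction),
                    type = "l", lty = 1, lwd = 2,
                    col = c("blue3", "darkorange2", "black"),
                    xlab = "position (um)", ylab = "stress", ...)
  graphics::legend("topright", c("motor", "viscous", "traction"),
                   col = c("blue3", "darkorange2", "black"), lwd = 2, bty = "n")
  invisible(x)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Scalar summaries of a flow profile
#'
#' Reports edge velocities, plateau means outside a 3-sigma neighbourhood of
#' the convergence zone, the peak retrograde speed, the centre-of-mass flow
#' `(1/L) * integral(v)` and the net substrate traction `integral(xi * v)`
#' (trapezoid rule). For symmetric parameters the last two vanish: symmetric
#' cells show constant flow toward the convergence zone but are stationary.
#' Which of `v_rear`, `plateau_left` or `com_velocity` best represents "cell
#' migration speed" is interpretive, so all are reported.
#'
#' @inheritParams stress_decomposition
#' @return Named list of class `flow_summary`.
#' @export
flow_summary <- function(profile, params = profile$params) {
  stopifnot(inherits(profile, "flow_profile"))
  validate_cell_params(params)
  x <- profile$positions
  v <- profile$velocities
  n <- length(x)
  lcut <- max(0, params$x_cz - 3 * params$sigma)
  rcut <- min(params$L, params$x_cz + 3 * params$sigma)
  out <- list(
    v_rear = v[1L],
    v_front = v[n],
    plateau_left = mean(v[x <= lcut]),
    plateau_right = mean(v[x >= rcut]),
    peak_retrograde = min(v),
    com_velocity = trapz(x, v) / params$L,
    net_traction = trapz(x, build_adhesion_profile(params, x) * v))
  class(out) <- "flow_summary"
  out
}

#' @export
print.flow_summary <- function(x, ...) {
  for (f in names(unclass(x)))
    cat(sprintf("  %-16s %.6g\n", f, x[[f]]))
  invisible(x)
}

#' Grid-refinement (Richardson) check
#'
#' Solves the force balance at `n_grid` and `2 * n_grid - 1` points and
#' reports the maximum difference at shared nodes relative to the peak speed.
#' The scheme is second order, so the report shrinks about fourfold per grid
#' doubling.
#'
#' @param params a [cell_params()] object.
#' @return List with `report` (max relative difference), `n_coarse`, `n_fine`.
#' @export
refine_check <- function(params) {
  validate_cell_params(params)
  coarse <- solve_flow(params)
  pf <- params
  pf$n_grid <- 2L * params$n_grid - 1L
  fine <- solve_flow(pf)
  vf <- fine$velocities[seq(1L, pf$n_grid, by = 2L)]
  vmax <- max(abs(fine$velocities))
  rep_val <- if (vmax == 0) 0 else max(abs(coarse$velocities - vf)) / vmax
  list(report = rep_val, n_coarse = params$n_grid, n_fine = pf$n_grid)
}
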