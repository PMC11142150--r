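# Peak motor stress coefficient: Fmax = sqrt(2) e^{-1/2} * amplitude / sigma
FMAX_COEF <- sqrt(2) * exp(-0.5)

#' Mechanical parameters of the 1D active-fluid cell model
#'
#' Constructs the full parameter set describing a cell projected onto one
#' dimension: a domain from the rear (`x = 0`) to the leading edge (`x = L`),
#' a Gaussian band of motor activity of width `sigma` centred on the
#' convergence zone `x_cz`, piecewise adhesion coefficients to the left and
#' right of the convergence zone, and an effective cytoskeletal viscosity.
#'
#' The motor forcing enters all equations only through the product of force
#' per motor and peak motor density, stored as the single field `amplitude`
#' (the two factors are not separately identifiable). Velocities are in the
#' lab (substrate) frame, positive toward the leading edge.
#'
#' @param L cell length (µm), rear to leading edge.
#' @param x_cz position of the convergence zone (µm), strictly inside `(0, L)`.
#' @param sigma width of the Gaussian motor distribution (µm).
#' @param amplitude combined motor forcing `f * M0` (stress units, e.g. pN/µm).
#' @param mu effective viscosity (stress · time).
#' @param xi_left,xi_right adhesion coefficients left/right of the convergence
#'   zone (stress · time / length). Both must be positive.
#' @param n_grid number of uniformly spaced grid points for numerical solves
#'   (at least 51; default 2001).
#' @param smooth_width optional half-width (µm) of a sigmoidal blend between
#'   `xi_left` and `xi_right`; `0` (default) gives a sharp step with the
#'   convergence-zone node assigned `xi_right` (right-closed convention).
#' @param velocity_unit free-text label attached to velocities on output;
#'   carried through untouched, never converted.
#'
#' @return An object of class `cell_params` (a validated list).
#' @seealso [cell_params_from_ratios()] for the ratio parameterization used
#'   when fitting data, [solve_flow()], [scalar_summaries()].
#' @examples
#' p <- cell_params(L = 20, x_cz = 10, sigma = 1, amplitude = 10,
#'                  mu = 1000, xi_left = 1000)
#' scalar_summaries(p)$lam  # 2
#' @export
cell_params <- function(L, x_cz, sigma, amplitude, mu, xi_left,
                        xi_right = xi_left, n_grid = 2001, smooth_width = 0,
                        velocity_unit = "um/min") {
  p <- structure(
    list(L = as.numeric(L), x_cz = as.numeric(x_cz), sigma = as.numeric(sigma),
         amplitude = as.numeric(amplitude), mu = as.numeric(mu),
         xi_left = as.numeric(xi_left), xi_right = as.numeric(xi_right),
         n_grid = as.integer(n_grid), smooth_width = as.numeric(smooth_width),
         velocity_unit = as.character(velocity_unit)),
    class = "cell_params")
  validate_cell_params(p)
  p
}

#' Build model parameters from dimensionless ratios
#'
#' Constructor matching the parameterization in which fitted values are
#' reported: the left adhesion coefficient is normalized to 1 and the model is
#' specified through `xi_ratio = xi_right/xi_left`,
#' `force_scale = Fmax/xi_left` (peak motor stress over left adhesion, units
#' of velocity) and `mu_ratio = mu/xi_left` (µm²). The motor amplitude is
#' recovered from `force_scale` via `Fmax = sqrt(2) exp(-1/2) amplitude / sigma`.
#'
#' @param sigma motor distribution width (µm).
#' @param x_cz convergence-zone position (µm).
#' @param L cell length (µm).
#' @param xi_ratio right-to-left adhesion ratio.
#' @param force_scale peak motor stress over left adhesion (velocity units).
#' @param mu_ratio viscosity over left adhesion (µm²).
#' @inheritParams cell_params
#' @return An object of class `cell_params` with `xi_left = 1`.
#' @examples
#' p <- cell_params_from_ratios(sigma = 1, x_cz = 15, L = 30, xi_ratio = 1,
#'                              force_scale = 1.5, mu_ratio = 500)
#' @export
cell_params_from_ratios <- function(sigma, x_cz, L, xi_ratio, force_scale,
                                    mu_ratio, n_grid = 2001, smooth_width = 0,
                                    velocity_unit = "um/min") {
  cell_params(L = L, x_cz = x_cz, sigma = sigma,
              amplitude = force_scale * sigma / FMAX_COEF,
              mu = mu_ratio, xi_left = 1, xi_right = xi_ratio,
              n_grid = n_grid, smooth_width = smooth_width,
              velocity_unit = velocity_unit)
}

validate_cell_params <- function(p) {
  stopifnot(is.list(p))
  num1 <- function(v) length(v) == 1L && is.finite(v)
  for (f in c("L", "x_cz", "sigma", "amplitude", "mu", "xi_left", "xi_right",
              "smooth_width"))
    if (!num1(p[[f]])) stop("parameter '", f, "' must be a finite scalar",
                            call. = FALSE)
  if (p$L <= 0) stop("L must be > 0", call. = FALSE)
  if (p$x_cz <= 0 || p$x_cz >= p$L)
    stop("x_cz must lie strictly inside (0, L)", call. = FALSE)
  if (p$sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (p$amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (p$mu <= 0) stop("mu must be > 0", call. = FALSE)
  if (p$xi_left <= 0 || p$xi_right <= 0)
    stop("adhesion coefficients must be > 0 (a free, unattached cell edge is ",
         "outside the steady-state model)", call. = FALSE)
  if (p$smooth_width < 0) stop("smooth_width must be >= 0", call. = FALSE)
  if (is.na(p$n_grid) || p$n_grid < 51L)
    stop("n_grid must be at least 51", call. = FALSE)
  invisible(p)
}

#' @export
print.cell_params <- function(x, ...) {
  cat("1D active-fluid cell model parameters\n")
  cat(sprintf("  domain:    L = %g um, %d grid points (dx = %.4g um)\n",
              x$L, x$n_grid, x$L / (x$n_grid - 1)))
  cat(sprintf("  motors:    amplitude f*M0 = %g, sigma = %g um, x_cz = %g um\n",
              x$amplitude, x$sigma, x$x_cz))
  cat(sprintf("  adhesion:  xi_left = %g, xi_right = %g (ratio %.4g)%s\n",
              x$xi_left, x$xi_right, x$xi_right / x$xi_left,
              if (x$smooth_width > 0)
                sprintf(", smoothed over +/- %g um", x$smooth_width) else ""))
  cat(sprintf("  viscosity: mu = %g  (lambda = %.4g, dissipation length %.4g um)\n",
              x$mu, lambda_param(x$mu / x$xi_left, x$sigma),
              dissipation_length(x$mu, x$xi_left)))
  invisible(x)
}

#' Closed-form scalar summaries of a parameter set
#'
#' Evaluates the analytic quantities of the model: peak motor stress
#' `f_max`, its locations `x_c_left`/`x_c_right` at `x_cz -/+ sigma/sqrt(2)`,
#' the dimensionless parameter `lam = 2 mu / (sigma^2 xi_left)`, the
#' dissipation length `ell = sqrt(mu/xi_left)` and the flow-speed estimate
#' `v_c = (f_max/xi_left)/(1 + lam)` at the stress peak.
#'
#' @param params a [cell_params()] object.
#' @return A named list with elements `f_max`, `x_c_left`, `x_c_right`,
#'   `lam`, `ell`, `v_c`.
#' @export
scalar_summaries <- function(params) {
  validate_cell_params(params)
  xc <- peak_stress_locations(params)
  f_max <- max_motor_stress(params)
  lam <- lambda_param(params$mu / params$xi_left, params$sigma)
  list(f_max = f_max,
       x_c_left = xc[[1L]], x_c_right = xc[[2L]],
       lam = lam,
       ell = dissipation_length(params$mu, params$xi_left),
       v_c = vc_estimate(f_max, params$xi_left, lam))
}

grid_positions <- function(params) {
  seq(0, params$L, length.out = params$n_grid)
}

# compact identifier for provenance lines and grid-match checks
params_id <- function(params) {
  paste(formatC(c(params$L, params$x_cz, params$sigma, params$amplitude,
                  params$mu, params$xi_left, params$xi_right,
                  params$smooth_width, params$n_grid),
                format = "g", digits = 15), collapse = "|")
}
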