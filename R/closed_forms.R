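#' Gaussian motor density
#'
#' Steady-state linear density of force-generating motors,
#' `M(x) = amplitude * exp(-((x - x_cz)/sigma)^2)`, expressed on the combined
#' scale `amplitude = f * M0` so that multiplying by the contractile force per
#' motor is already folded in.
#'
#' @param params a [cell_params()] object.
#' @param x positions (µm); any finite numeric vector.
#' @return Motor forcing density at `x`.
#' @export
motor_density <- function(params, x) {
  validate_cell_params(params)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("positions must be finite numeric values", call. = FALSE)
  params$amplitude * exp(-((x - params$x_cz) / params$sigma)^2)
}

#' Motor-induced contractile stress
#'
#' The active stress is the gradient of the motor density:
#' `F_m(x) = -2 amplitude / sigma^2 * (x - x_cz) * exp(-((x - x_cz)/sigma)^2)`.
#' It is antisymmetric about the convergence zone: positive to the left
#' (pulling material rightward, toward the zone) and negative to the right.
#'
#' @inheritParams motor_density
#' @return Motor stress at `x`.
#' @export
motor_stress <- function(params, x) {
  validate_cell_params(params)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("positions must be finite numeric values", call. = FALSE)
  u <- x - params$x_cz
  -2 * params$amplitude / params$sigma^2 * u * exp(-(u / params$sigma)^2)
}

#' Peak motor stress
#'
#' `Fmax = sqrt(2) * exp(-1/2) * amplitude / sigma`, approximately
#' `0.86 * amplitude / sigma`: the magnitude of the motor stress at its two
#' extrema `x_cz -/+ sigma/sqrt(2)`.
#'
#' @inheritParams motor_density
#' @return Scalar peak stress.
#' @export
max_motor_stress <- function(params) {
  validate_cell_params(params)
  FMAX_COEF * params$amplitude / params$sigma
}

#' Locations of peak motor stress
#'
#' Stationary points of the motor stress, at `x_cz -/+ sigma/sqrt(2)`.
#' Their spacing is `sigma * sqrt(2)`.
#'
#' @inheritParams motor_density
#' @return Named numeric vector `c(left = ..., right = ...)`.
#' @export
peak_stress_locations <- function(params) {
  validate_cell_params(params)
  d <- params$sigma / sqrt(2)
  c(left = params$x_cz - d, right = params$x_cz + d)
}

#' Dimensionless dissipation parameter
#'
#' `lambda = 2 * mu_over_xi / sigma^2`, the squared ratio of the dissipation
#' length `sqrt(mu/xi)` to the motor width `sigma` (times 2). Small `lambda`
#' means motor forces are dissipated by substrate traction and flow is
#' localized near the convergence zone; large `lambda` means internal viscous
#' dissipation dominates and flow is near-uniform on each side.
#'
#' @param mu_over_xi viscosity over adhesion, `mu/xi` (µm²); must be > 0.
#' @param sigma motor distribution width (µm); must be > 0.
#' @return Scalar `lambda`.
#' @examples
#' lambda_param(1000 / 1000, 1) # 2
#' lambda_param(1000 / 100, 1)  # 20
#' @export
lambda_param <- function(mu_over_xi, sigma) {
  if (any(!is.finite(mu_over_xi)) || any(mu_over_xi <= 0))
    stop("mu_over_xi must be positive", call. = FALSE)
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("sigma must be positive", call. = FALSE)
  2 * mu_over_xi / sigma^2
}

#' Characteristic dissipation length
#'
#' `ell = sqrt(mu/xi)`: the distance over which internal stress decays in a
#' viscous medium coupled to the substrate by velocity-proportional traction.
#'
#' @param mu viscosity (> 0).
#' @param xi adhesion coefficient (> 0).
#' @return Length in µm.
#' @export
dissipation_length <- function(mu, xi) {
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be positive", call. = FALSE)
  if (any(!is.finite(xi)) || any(xi <= 0)) stop("xi must be positive", call. = FALSE)
  sqrt(mu / xi)
}

#' Analytic flow-speed estimate at the stress peak
#'
#' `v_c = (f_max / xi_left) / (1 + lam)`: the balance of peak motor stress
#' against traction and viscous dissipation at `x_c`. Decreases monotonically
#' in `lam` and tends to `f_max/xi_left` as `lam -> 0`.
#'
#' @param f_max peak motor stress.
#' @param xi_left adhesion coefficient on the lagging side.
#' @param lam dimensionless parameter, see [lambda_param()].
#' @return Flow speed estimate.
#' @export
vc_estimate <- function(f_max, xi_left, lam) {
  (f_max / xi_left) / (1 + lam)
}

#' Viscous/traction partition of the peak motor stress
#'
#' At the stress peak the motor stress is balanced by internal viscous stress
#' and substrate traction in proportions set solely by `lam`:
#' `|F_visc| = f_max * lam / (1 + lam)` and `|T| = f_max / (1 + lam)`.
#' The two magnitudes sum to `f_max` exactly. For small `lam` motor forces
#' are dissipated primarily by external traction; for large `lam` they are
#' dissipated internally.
#'
#' @param f_max peak motor stress (>= 0).
#' @param lam dimensionless parameter (>= 0).
#' @return Named vector `c(viscous = ..., traction = ...)` of magnitudes.
#' @export
stress_partition <- function(f_max, lam) {
  stopifnot(f_max >= 0, lam >= 0)
  c(viscous = f_max * lam / (1 + lam), traction = f_max / (1 + lam))
}
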