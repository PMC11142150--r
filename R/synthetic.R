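with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
          else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Generate a synthetic observed velocity profile
#'
#' Solves the forward model and samples it on an evenly spaced observation
#' grid (default 0.2 µm spacing, a typical kymograph pixel size), then adds
#' independent Gaussian noise. Two noise structures are supported:
#' `"additive"` noise with standard deviation `noise_sd` times the peak
#' speed at every point, and `"multiplicative"` noise with standard deviation
#' `noise_sd` times the local speed `|v(x)|` — the scatter structure of
#' velocities measured from kymograph streak slopes, whose uncertainty scales
#' with the slope itself.
#'
#' With the same seed the output is identical; with `noise_sd = 0` the
#' profile equals the solver output at the sampled positions exactly.
#'
#' @param x a preset name, a `flow_preset`, or a [cell_params()] object.
#' @param noise_sd noise standard deviation as a fraction (see `noise_type`).
#' @param seed integer seed for the noise; `NULL` leaves the RNG state alone.
#' @param noise_type `"additive"` (fraction of peak speed, default) or
#'   `"multiplicative"` (fraction of local speed).
#' @param spacing observation grid spacing (µm).
#' @return An [observed_profile()] with provenance attributes
#'   (`params`, `noise_sd`, `noise_type`, `seed`).
#' @export
generate_profile <- function(x, noise_sd = 0, seed = NULL,
                             noise_type = c("additive", "multiplicative"),
                             spacing = 0.2) {
  noise_type <- match.arg(noise_type)
  stopifnot(noise_sd >= 0, spacing > 0)
  params <- if (inherits(x, "cell_params")) x else preset_params(x)
  sol <- solve_flow(params)
  xs <- seq(0, params$L, length.out = max(15L, round(params$L / spacing) + 1L))
  v0 <- stats::approx(sol$positions, sol$velocities, xout = xs)$y
  sd_pt <- if (noise_sd == 0) rep(0, length(xs))
           else if (noise_type == "additive")
             rep(noise_sd * max(abs(v0)), length(xs))
           else noise_sd * abs(v0)
  v <- if (noise_sd == 0) v0
       else with_seed(seed, v0 + stats::rnorm(length(v0), 0, sd_pt))
  prof <- observed_profile(xs, v, sd = if (noise_sd > 0) sd_pt else NULL,
                           velocity_unit = params$velocity_unit)
  attr(prof, "params") <- params
  attr(prof, "noise_sd") <- noise_sd
  attr(prof, "noise_type") <- noise_type
  attr(prof, "seed") <- seed
  prof
}

#' Generate a kymograph-like tracer matrix
#'
#' Seeds point tracers uniformly at random along the cell at time zero,
#' advects each by `dx/dt = v(x)` with fixed-step 4th-order Runge-Kutta
#' integration (velocities interpolated from the profile, clamped at the
#' edges), and renders the trajectories as Gaussian-blurred streaks in a
#' space-time intensity matrix normalized to `[0, 1]` — the synthetic
#' analogue of a kymograph taken along the flow axis. Where the flow
#' converges, streaks slope toward the convergence zone.
#'
#' @param profile a `flow_profile` or [observed_profile()].
#' @param duration total imaged time (same time unit as the velocities).
#' @param tracer_count number of tracers (>= 1).
#' @param seed integer seed for the initial tracer positions.
#' @param n_frames number of time samples (rows).
#' @param pixel_size spatial pixel size (µm, columns).
#' @param blur Gaussian streak half-width in pixels.
#' @return Object of class `synthetic_kymograph`: list with `intensity`
#'   (time rows x space columns), `pixel_size`, `frame_interval`,
#'   `tracer_count` and the tracer `paths` matrix (frames x tracers).
#' @export
generate_kymograph <- function(profile, duration, tracer_count = 40L,
                               seed = NULL, n_frames = 100L, pixel_size = 0.2,
                               blur = 1.5) {
  stopifnot(duration > 0, tracer_count >= 1, n_frames >= 2)
  x <- profile$positions
  v <- profile$velocities
  L0 <- min(x); L1 <- max(x)
  vel <- function(p) stats::approx(x, v, xout = pmin(pmax(p, L0), L1),
                                   rule = 2)$y
  dt_frame <- duration / (n_frames - 1L)
  nsub <- 5L
  dt <- dt_frame / nsub
  pos <- with_seed(seed, stats::runif(tracer_count, L0, L1))
  paths <- matrix(NA_real_, n_frames, tracer_count)
  paths[1L, ] <- pos
  for (fr in 2:n_frames) {
    for (s in seq_len(nsub)) {
      k1 <- vel(pos)
      k2 <- vel(pos + dt / 2 * k1)
      k3 <- vel(pos + dt / 2 * k2)
      k4 <- vel(pos + dt * k3)
      pos <- pos + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      pos <- pmin(pmax(pos, L0), L1)
    }
    paths[fr, ] <- pos
  }
  ncol_px <- max(2L, floor((L1 - L0) / pixel_size) + 1L)
  centers <- L0 + (seq_len(ncol_px) - 1L) * pixel_size
  img <- matrix(0, n_frames, ncol_px)
  for (fr in seq_len(n_frames))
    for (tr in seq_len(tracer_count))
      img[fr, ] <- img[fr, ] +
        exp(-((centers - paths[fr, tr]) / (blur * pixel_size))^2 / 2)
  img <- img / max(img)
  structure(list(intensity = img, pixel_size = pixel_size,
                 frame_interval = dt_frame, tracer_count = tracer_count,
                 paths = paths),
            class = "synthetic_kymograph")
}

#' @export
print.synthetic_kymograph <- function(x, ...) {
  cat(sprintf("synthetic kymograph: %d frames x %d pixels (%g um/px, frame interval %g), %d tracers\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size,
              x$frame_interval, x$tracer_count))
  invisible(x)
}

#' @export
plot.synthetic_kymograph <- function(x, ...) {
  graphics::image(t(x$intensity[rev(seq_len(nrow(x$intensity))), ]),
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  xlab = "position", ylab = "time", ...)
  invisible(x)
}

#' Synthetic parameter-recovery experiment
#'
#' For each noise level, generates `replicates` noisy profiles from a preset
#' (seeds `base_seed ... base_seed + replicates - 1`), fits each with
#' [fit_flow()] and summarizes the relative errors of the recovered ratios
#' against the generating values. Fit failures are counted, not fatal.
#'
#' @param preset preset name or `flow_preset`.
#' @param noise_sds numeric vector of noise levels (fractions).
#' @param replicates replicates per noise level (>= 1).
#' @param base_seed first seed.
#' @param noise_type passed to [generate_profile()].
#' @param control a [fit_control()] list.
#' @return Data frame with one row per (noise level, parameter): the median
#'   and IQR of the relative error `|estimate/true - 1|`, the median
#'   estimate, the generating value, and counts of successful/failed fits.
#' @export
recovery_experiment <- function(preset, noise_sds = c(0, 0.02),
                                replicates = 5L, base_seed = 0L,
                                noise_type = c("additive", "multiplicative"),
                                control = fit_control()) {
  noise_type <- match.arg(noise_type)
  stopifnot(replicates >= 1)
  if (is.character(preset)) preset <- flow_preset(preset)
  params <- preset_params(preset, n_grid = control$n_grid)
  truth <- c(xi_ratio = preset$xi_ratio, force_scale = preset$force_scale,
             mu_ratio = preset$mu_ratio)
  out <- NULL
  for (sd in noise_sds) {
    est <- matrix(NA_real_, replicates, 3L,
                  dimnames = list(NULL, names(truth)))
    fails <- 0L
    for (r in seq_len(replicates)) {
      fit <- tryCatch({
        prof <- generate_profile(params, noise_sd = sd,
                                 seed = base_seed + r - 1L,
                                 noise_type = noise_type)
        fit_flow(prof, control)
      }, error = function(e) NULL)
      if (is.null(fit)) fails <- fails + 1L
      else est[r, ] <- c(fit$xi_ratio, fit$force_scale, fit$mu_ratio)
    }
    for (p in names(truth)) {
      rel <- abs(est[, p] / truth[[p]] - 1)
      out <- rbind(out, data.frame(
        noise_sd = sd, parameter = p, true = truth[[p]],
        median_estimate = stats::median(est[, p], na.rm = TRUE),
        median_rel_error = stats::median(rel, na.rm = TRUE),
        iqr_rel_error = stats::IQR(rel, na.rm = TRUE),
        n_ok = replicates - fails, n_fail = fails))
    }
  }
  out
}
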