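#' Read an observed velocity profile from delimited text
#'
#' Parses a two- or three-column table (position, velocity, optional standard
#' deviation). The delimiter (comma, tab or whitespace) is auto-detected,
#' lines starting with `#` are ignored, and an optional header row is
#' recognized by a non-numeric first field.
#'
#' @param path file to read.
#' @param velocity_unit unit label to attach (metadata only).
#' @return An [observed_profile()].
#' @export
read_profile <- function(path, velocity_unit = "um/min") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) == 0L) stop("no data lines in ", path, call. = FALSE)
  first <- raw[keep[1L]]
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  split1 <- function(s) {
    f <- if (sep == "") strsplit(trimws(s), "\\s+")[[1L]]
         else trimws(strsplit(s, sep, fixed = TRUE)[[1L]])
    f[nzchar(f)]
  }
  fields1 <- split1(first)
  has_header <- suppressWarnings(any(is.na(as.numeric(fields1))))
  data_idx <- if (has_header) keep[-1L] else keep
  if (length(data_idx) == 0L) stop("no data rows in ", path, call. = FALSE)
  rows <- lapply(data_idx, function(i) {
    f <- suppressWarnings(as.numeric(split1(raw[i])))
    if (length(f) < 2L)
      stop("line ", i, " of ", path, " has fewer than 2 numeric columns",
           call. = FALSE)
    if (any(is.na(f) | !is.finite(f)))
      stop("non-finite or non-numeric entry on line ", i, " of ", path,
           call. = FALSE)
    f
  })
  ncols <- min(vapply(rows, length, integer(1)))
  m <- do.call(rbind, lapply(rows, function(r) r[seq_len(ncols)]))
  if (any(diff(m[, 1L]) <= 0)) {
    bad <- data_idx[which(diff(m[, 1L]) <= 0)[1L] + 1L]
    stop("positions are not strictly increasing at line ", bad, " of ", path,
         call. = FALSE)
  }
  # permissive construction: short tables are readable (and writable again);
  # the >= 15 point requirement applies when a profile is fitted
  structure(list(positions = m[, 1L], velocities = m[, 2L],
                 sd = if (ncols >= 3L) m[, 3L] else NULL,
                 velocity_unit = velocity_unit),
            class = "observed_profile")
}

provenance_lines <- function(params = NULL, seed = NULL, extra = NULL) {
  c(sprintf("# generated by cortexflow %s",
            as.character(utils::packageVersion("cortexflow"))),
    sprintf("# date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    if (!is.null(params))
      sprintf("# params: L=%g x_cz=%g sigma=%g amplitude=%g mu=%g xi_left=%g xi_right=%g smooth_width=%g n_grid=%d",
              params$L, params$x_cz, params$sigma, params$amplitude,
              params$mu, params$xi_left, params$xi_right, params$smooth_width,
              params$n_grid),
    if (!is.null(params))
      sprintf("# velocity_unit: %s", params$velocity_unit),
    if (!is.null(seed)) sprintf("# seed: %s", format(seed)),
    extra)
}

#' Write a velocity profile as delimited text
#'
#' Columns `position, velocity[, sd]`, comma-separated, preceded by
#' `#`-prefixed provenance comments (parameters, seed, version, timestamp).
#'
#' @param profile a `flow_profile` or [observed_profile()].
#' @param path output file.
#' @param seed optional seed to record in the provenance comments.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, seed = NULL) {
  params <- profile$params %||% attr(profile, "params")
  d <- as.data.frame(profile)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path,
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(provenance_lines(params, seed %||% attr(profile, "seed")), con)
  writeLines(paste(names(d), collapse = ","), con)
  utils::write.table(format(d, digits = 15, trim = TRUE, scientific = NA),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a stress decomposition as delimited text
#'
#' Columns `position, motor_stress, viscous_stress, traction, residual` with
#' `#`-prefixed provenance comments.
#'
#' @param stresses a [stress_decomposition()] result.
#' @param path output file.
#' @inheritParams write_profile
#' @return `path`, invisibly.
#' @export
write_stresses <- function(stresses, path, seed = NULL) {
  stopifnot(inherits(stresses, "stress_decomposition"))
  d <- as.data.frame(stresses)
  names(d) <- c("position", "motor_stress", "viscous_stress", "traction",
                "residual")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path,
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(provenance_lines(attr(stresses, "params"), seed), con)
  writeLines(paste(names(d), collapse = ","), con)
  utils::write.table(format(d, digits = 15, trim = TRUE, scientific = NA),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a fit result as a structured key-value report
#'
#' One `key: value` pair per line covering the five recovered parameters,
#' `lambda`, convergence diagnostics and tolerances, preceded by provenance
#' comments.
#'
#' @param fit a [fit_flow()] result.
#' @param path output file.
#' @param seed optional seed to record.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, seed = NULL) {
  stopifnot(inherits(fit, "flow_fit"))
  fmt <- function(x) formatC(x, format = "g", digits = 10)
  lines <- c(
    provenance_lines(fit$params, seed),
    paste0("x_cz: ", fmt(fit$x_cz)),
    paste0("sigma: ", fmt(fit$sigma)),
    paste0("xi_ratio: ", fmt(fit$xi_ratio)),
    paste0("force_scale: ", fmt(fit$force_scale)),
    paste0("mu_ratio: ", fmt(fit$mu_ratio)),
    paste0("lambda: ", fmt(fit$lam)),
    paste0("rms_residual: ", fmt(fit$rms_residual)),
    paste0("nrmse: ", fmt(fit$nrmse)),
    paste0("n_iterations: ", fit$n_iterations),
    paste0("converged: ", tolower(fit$converged)),
    paste0("mu_lower_bound: ", tolower(fit$mu_lower_bound)),
    paste0("margin_left: ", fmt(fit$margins[[1L]])),
    paste0("margin_right: ", fmt(fit$margins[[2L]])),
    paste0("tolerance: ", fmt(fit$control$tol)),
    paste0("smoothing_window: ", fit$control$window),
    paste0("velocity_unit: ", fit$profile$velocity_unit))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Write a bundle of results to a directory
#'
#' Writes up to three files: `profile.csv` (velocity profile),
#' `stresses.csv` (stress decomposition) and `summary.txt` (key-value
#' report: fit parameters if a fit is present, otherwise flow summary
#' fields). Output is byte-deterministic for fixed inputs apart from the
#' timestamp comment.
#'
#' @param bundle a named list with any of `profile` (flow or observed
#'   profile), `stresses` ([stress_decomposition()]), `fit` ([fit_flow()]
#'   result), `summary` ([flow_summary()]), `seed`.
#' @param dir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(bundle, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir, call. = FALSE)
  written <- character(0)
  if (!is.null(bundle$profile)) {
    f <- file.path(dir, "profile.csv")
    write_profile(bundle$profile, f, seed = bundle$seed)
    written <- c(written, f)
  }
  if (!is.null(bundle$stresses)) {
    f <- file.path(dir, "stresses.csv")
    write_stresses(bundle$stresses, f, seed = bundle$seed)
    written <- c(written, f)
  }
  if (!is.null(bundle$fit)) {
    f <- file.path(dir, "summary.txt")
    write_fit_report(bundle$fit, f, seed = bundle$seed)
    written <- c(written, f)
  } else if (!is.null(bundle$summary)) {
    f <- file.path(dir, "summary.txt")
    s <- unclass(bundle$summary)
    writeLines(c(provenance_lines(bundle$params, bundle$seed),
                 sprintf("%s: %s", names(s),
                         formatC(unlist(s), format = "g", digits = 10))), f)
    written <- c(written, f)
  }
  if (!is.null(bundle$kymograph)) {
    f <- file.path(dir, "kymograph.csv")
    utils::write.table(format(bundle$kymograph$intensity, digits = 6,
                              trim = TRUE),
                       f, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}

.config_schema <- list(
  mode = NULL,
  seed = NULL,
  velocity_unit = NULL,
  params = c("ratio", "absolute"),
  ratio = c("sigma", "x_cz", "L", "xi_ratio", "force_scale", "mu_ratio",
            "smooth_width"),
  absolute = c("sigma", "x_cz", "L", "amplitude", "mu", "xi_left", "xi_right",
               "smooth_width"),
  grid = c("n_grid"),
  noise = c("sd", "seed", "type"),
  fit = c("window", "margin", "tol", "max_iter", "n_grid"),
  output = c("dir"))

#' Read and validate a run configuration file
#'
#' YAML configuration with blocks `params` (holding either a `ratio` or an
#' `absolute` parameter block), `grid`, `noise`, `fit`, `output`, plus scalar
#' keys `mode`, `seed` and `velocity_unit`. Unknown keys anywhere are
#' rejected so typos fail fast.
#'
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a key-value mapping", call. = FALSE)
  check_keys <- function(block, allowed, where) {
    bad <- setdiff(names(block), allowed)
    if (length(bad))
      stop("unknown config key", if (length(bad) > 1) "s", " in ", where,
           ": ", paste(bad, collapse = ", "), call. = FALSE)
  }
  check_keys(cfg, c("mode", "seed", "velocity_unit", "params", "grid",
                    "noise", "fit", "output"), "top level")
  if (!is.null(cfg$mode) &&
      !cfg$mode %in% c("simulate", "fit", "synth", "preset"))
    stop("mode must be one of simulate, fit, synth, preset", call. = FALSE)
  if (!is.null(cfg$seed) &&
      (!is.numeric(cfg$seed) || cfg$seed < 0 || cfg$seed != round(cfg$seed)))
    stop("seed must be a non-negative integer", call. = FALSE)
  if (!is.null(cfg$params)) {
    check_keys(cfg$params, .config_schema$params, "'params'")
    if (!is.null(cfg$params$ratio))
      check_keys(cfg$params$ratio, .config_schema$ratio, "'params$ratio'")
    if (!is.null(cfg$params$absolute))
      check_keys(cfg$params$absolute, .config_schema$absolute,
                 "'params$absolute'")
  }
  for (b in c("grid", "noise", "fit", "output"))
    if (!is.null(cfg[[b]]))
      check_keys(cfg[[b]], .config_schema[[b]], paste0("'", b, "'"))
  cfg
}

config_to_params <- function(cfg, n_grid = NULL) {
  pb <- cfg$params
  if (is.null(pb) || (is.null(pb$ratio) && is.null(pb$absolute)))
    stop("config has no 'params: ratio:' or 'params: absolute:' block",
         call. = FALSE)
  ng <- n_grid %||% cfg$grid$n_grid %||% 2001L
  vu <- cfg$velocity_unit %||% "um/min"
  if (!is.null(pb$ratio))
    do.call(cell_params_from_ratios,
            c(pb$ratio, list(n_grid = ng, velocity_unit = vu)))
  else
    do.call(cell_params, c(pb$absolute, list(n_grid = ng, velocity_unit = vu)))
}
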