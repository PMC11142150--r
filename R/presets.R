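# Representative fitted ratio parameters for the five motility modes.
# Domains (L, x_cz) are package defaults placing the convergence zone as in
# the corresponding cell geometries: centred for cytokinesis, near the front
# for the migratory modes, inside the growth cone for the neuronal modes.
# The Fmax/xi_left column carries an unresolved velocity-unit label and is
# never converted.
.presets <- list(
  cytokinesis = list(
    name = "cytokinesis", sigma = 1.0, xi_ratio = 1.0, force_scale = 1.5,
    mu_ratio = 5.0e2, lam_order = 3L, L = 30, x_cz = 15,
    velocity_unit = "um/min (unresolved)",
    lam_order_consistent = TRUE,
    note = paste("Symmetric adhesion; convergence zone at the cleavage",
                 "furrow. mu/xi_left is ambiguous in the source fits and is",
                 "set to 5.0e2, the value consistent with sigma = 1 and the",
                 "reported lambda ~ 10^3.")),
  amoeboid_migration = list(
    name = "amoeboid_migration", sigma = 9.0, xi_ratio = 4.0e3,
    force_scale = 1.52, mu_ratio = 5.4e4, lam_order = 3L, L = 60, x_cz = 35,
    velocity_unit = "um/min (unresolved)",
    lam_order_consistent = TRUE,
    note = paste("Wide convergence zone; strong front adhesion with a weakly",
                 "adhering uropod (large xi_right/xi_left).")),
  mesenchymal_migration = list(
    name = "mesenchymal_migration", sigma = 4.7, xi_ratio = 6.5,
    force_scale = 1.65, mu_ratio = 5.0e2, lam_order = 1L, L = 40, x_cz = 28,
    velocity_unit = "um/min (unresolved)",
    lam_order_consistent = FALSE,
    note = paste("Strong, weakly graded adhesion. The reported lambda order",
                 "(~10^1) is inconsistent with 2*mu_ratio/sigma^2 ~ 45",
                 "(order 10^2); the printed values are kept verbatim and",
                 "this row is excluded from lambda-order consistency checks.")),
  neuronal_migration = list(
    name = "neuronal_migration", sigma = 1.0, xi_ratio = 6.0e4,
    force_scale = 3.2e4, mu_ratio = 4.5e7, lam_order = 8L, L = 60, x_cz = 55,
    velocity_unit = "um/min (unresolved)",
    lam_order_consistent = TRUE,
    note = paste("Narrow convergence zone in the growth cone; very weak",
                 "adhesion under the leading process gives near-uniform",
                 "anterograde flow (lambda ~ 10^8).")),
  axon_outgrowth = list(
    name = "axon_outgrowth", sigma = 1.0, xi_ratio = 1.2, force_scale = 1.0,
    mu_ratio = 2.9e3, lam_order = 4L, L = 100, x_cz = 95,
    velocity_unit = "um/min (unresolved)",
    lam_order_consistent = TRUE,
    note = paste("Adhesion along the axon and cell body dissipates stress,",
                 "so bulk anterograde flow decays with distance from the",
                 "growth cone and the cell body is stationary.")))

#' Names of the built-in motility-mode presets
#' @return Character vector of the five preset names.
#' @export
preset_names <- function() names(.presets)

#' Fitted parameter preset for a motility mode
#'
#' Returns the representative ratio-parameter set for one of the five
#' motility modes: motor width `sigma`, adhesion ratio `xi_right/xi_left`,
#' motor strength over left adhesion `Fmax/xi_left`, viscosity over left
#' adhesion `mu/xi_left`, the order of magnitude of `lambda`, and default
#' domain geometry (`L`, `x_cz`).
#'
#' @param name one of `"cytokinesis"`, `"amoeboid_migration"`,
#'   `"mesenchymal_migration"`, `"neuronal_migration"`, `"axon_outgrowth"`.
#' @return Object of class `flow_preset` (a named list).
#' @examples
#' flow_preset("amoeboid_migration")$xi_ratio  # 4000
#' @export
flow_preset <- function(name) {
  if (length(name) != 1L || !name %in% names(.presets))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid names: ", paste(names(.presets), collapse = ", "),
         call. = FALSE)
  structure(.presets[[name]], class = "flow_preset")
}

#' @export
print.flow_preset <- function(x, ...) {
  cat(sprintf("preset '%s'\n", x$name))
  cat(sprintf("  sigma = %g um, xi_right/xi_left = %g, Fmax/xi_left = %g,\n",
              x$sigma, x$xi_ratio, x$force_scale))
  cat(sprintf("  mu/xi_left = %g um^2, lambda ~ 10^%d, domain L = %g um, x_cz = %g um\n",
              x$mu_ratio, x$lam_order, x$L, x$x_cz))
  cat("  ", x$note, "\n", sep = "")
  invisible(x)
}

#' Model parameters for a preset
#'
#' Converts a preset (or its name) into a full [cell_params()] object with
#' `xi_left = 1`.
#'
#' @param preset a `flow_preset` or preset name.
#' @param ... overrides passed to [cell_params_from_ratios()] (e.g. `n_grid`).
#' @return A [cell_params()] object.
#' @export
preset_params <- function(preset, ...) {
  if (is.character(preset)) preset <- flow_preset(preset)
  stopifnot(inherits(preset, "flow_preset"))
  args <- list(sigma = preset$sigma, x_cz = preset$x_cz, L = preset$L,
               xi_ratio = preset$xi_ratio, force_scale = preset$force_scale,
               mu_ratio = preset$mu_ratio,
               velocity_unit = preset$velocity_unit)
  over <- list(...)
  args[names(over)] <- over
  do.call(cell_params_from_ratios, args)
}
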