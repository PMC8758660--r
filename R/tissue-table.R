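## Packaged dielectric reference table. Columns beyond n = 2 may be absent for
## a tissue; relaxation times are stored in seconds (the literature table
## quotes tau1 in ps, tau2 in ns, tau3 in us, tau4 in ms).
.tissue_rows <- list(
  "Dry Skin" = list(
    eps_inf = 4.0, sigma_dc = 0.0002,
    disp = list(c(32.0, 7.23e-12, 0.00),
                c(1100, 32.48e-9, 0.00))),
  "Wet Skin" = list(
    eps_inf = 4.0, sigma_dc = 0.0004,
    disp = list(c(39.0, 7.96e-12, 0.10),
                c(280, 79.58e-9, 0.00),
                c(3.0e4, 1.59e-6, 0.16),
                c(3.0e4, 1.592e-3, 0.20))),
  "Fat" = list(
    eps_inf = 2.5, sigma_dc = 0.0350,
    disp = list(c(9.0, 7.96e-12, 0.20),
                c(35, 15.92e-9, 0.10),
                c(3.3e4, 159.15e-6, 0.05),
                c(1.0e7, 15.915e-3, 0.01))),
  "Muscle (Transversal)" = list(
    eps_inf = 4.0, sigma_dc = 0.2000,
    disp = list(c(50.0, 7.23e-12, 0.10),
                c(7000, 353.68e-9, 0.10),
                c(1.2e6, 318.31e-6, 0.10),
                c(2.5e7, 2.274e-3, 0.00))),
  "Muscle (Parallel)" = list(
    eps_inf = 4.0, sigma_dc = 0.2397,
    disp = list(c(50.0, 10.57e-12, 0.11),
                c(7000, 19.10e-9, 0.01),
                c(1.2e6, 725.47e-6, 0.32),
                c(2.5e7, 0.737e-3, 0.00))),
  "Bone" = list(
    eps_inf = 2.5, sigma_dc = 0.0700,
    disp = list(c(18.0, 13.26e-12, 0.22),
                c(300, 79.58e-9, 0.25),
                c(2.0e4, 159.15e-6, 0.20),
                c(2.0e7, 15.915e-3, 0.00)))
)

#' Default tissue dielectric table
#'
#' The packaged four-dispersion Cole-Cole parameters for the six knee tissues:
#' dry skin (stratum corneum and lucidum), wet skin (deeper epidermis and
#' dermis), subcutaneous fat, skeletal muscle excited transversally and
#' parallel to the fibers, and bone. The parallel-muscle row is the output of
#' the constrained anisotropic identification (see
#' [identify_parallel_parameters()]); the remaining rows follow the standard
#' literature parameterization.
#'
#' @return A named list of [cole_cole()] objects with class `"tissue_table"`;
#'   relaxation times in seconds, conductivities in S/m.
#' @export
default_tissue_table <- function() {
  tab <- lapply(names(.tissue_rows), function(nm) {
    row <- .tissue_rows[[nm]]
    cole_cole(row$eps_inf,
              lapply(row$disp, function(d)
                dispersion(delta_eps = d[1], tau = d[2], alpha = d[3])),
              row$sigma_dc, label = nm)
  })
  names(tab) <- names(.tissue_rows)
  structure(tab, class = "tissue_table")
}

required_tissues <- function() names(.tissue_rows)

validate_tissue_table <- function(table) {
  if (!inherits(table, "tissue_table") && !is.list(table))
    stop_validation("'table' must be a tissue_table")
  missing <- setdiff(required_tissues(), names(table))
  if (length(missing))
    stop_validation(paste0("tissue table is missing entries: ",
                           paste(missing, collapse = ", ")))
  invisible(table)
}

#' @export
print.tissue_table <- function(x, ...) {
  cat("Tissue dielectric table (", length(x), " tissues )\n", sep = "")
  for (nm in names(x))
    cat(sprintf("  %-22s eps_inf %5.1f  sigma_dc %.4f S/m  %d dispersions\n",
                nm, x[[nm]]$eps_inf, x[[nm]]$sigma_dc,
                length(x[[nm]]$dispersions)))
  invisible(x)
}

#' Default anisotropic muscle model
#'
#' Combines the transversal and parallel muscle rows of a tissue table into a
#' diagonal-tensor anisotropic permittivity with fibers along the limb axis.
#'
#' @param table A tissue table, by default [default_tissue_table()].
#' @param fiber_axis Unit fiber direction, default the limb longitudinal axis.
#' @return An [anisotropic_permittivity()] object.
#' @export
default_muscle_anisotropy <- function(table = default_tissue_table(),
                                      fiber_axis = c(0, 0, 1)) {
  validate_tissue_table(table)
  anisotropic_permittivity(parallel = table[["Muscle (Parallel)"]],
                           perpendicular = table[["Muscle (Transversal)"]],
                           fiber_axis = fiber_axis)
}

#' Write a tissue table to YAML
#'
#' One block per tissue with fields `eps_inf`, `sigma_dc_S_per_m` and
#' `dispersions` (each with `delta_eps`, `tau_s`, `alpha`).
#'
#' @param table A tissue table.
#' @param path Output file path.
#' @export
write_tissue_table <- function(table, path) {
  validate_tissue_table(table)
  out <- lapply(table, function(p) {
    list(eps_inf = p$eps_inf,
         sigma_dc_S_per_m = p$sigma_dc,
         dispersions = lapply(p$dispersions, function(d)
           list(delta_eps = d$delta_eps, tau_s = d$tau, alpha = d$alpha)))
  })
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Read a tissue table from YAML
#'
#' @param path File written by [write_tissue_table()] (or hand-edited in the
#'   same schema).
#' @return A `tissue_table`.
#' @export
read_tissue_table <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("no such file: ", path))
  raw <- yaml::read_yaml(path)
  tab <- lapply(names(raw), function(nm) {
    b <- raw[[nm]]
    cole_cole(b$eps_inf,
              lapply(b$dispersions, function(d)
                dispersion(d$delta_eps, d$tau_s, d$alpha)),
              b$sigma_dc_S_per_m, label = nm)
  })
  names(tab) <- names(raw)
  structure(tab, class = "tissue_table")
}
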