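#' Assembled personalized knee model
#'
#' Ties together a subject's five-layer geometry, a tissue dielectric table,
#' an electrode configuration and a forward model: either the mesh-free
#' layered surrogate (default, fast enough for fitting) or the 2D/3D
#' finite-element solver.
#'
#' @param profile A [subject_profile()].
#' @param tissues A tissue table (default [default_tissue_table()]).
#' @param forward `"surrogate"`, `"fem-2d"` or `"fem-3d"`.
#' @param electrodes An [electrode_config()]; default placement for the mode.
#' @param frequencies Default frequency grid of the model.
#' @param area_mm2 Current-tube cross-section of the surrogate; defaults to
#'   the drive-patch area.
#' @param resolution Mesh refinement level for the FEM modes.
#' @param calibrated Sex-calibrated fat-thickness mode (see
#'   [subcutaneous_fat_thickness()]).
#' @return An object of class `"knee_model"`.
#' @export
knee_model <- function(profile, tissues = default_tissue_table(),
                       forward = c("surrogate", "fem-2d", "fem-3d"),
                       electrodes = NULL,
                       frequencies = default_frequencies(),
                       area_mm2 = NULL, resolution = 1, calibrated = TRUE) {
  forward <- match.arg(forward)
  validate_tissue_table(tissues)
  stack <- personalize_thicknesses(profile, calibrated = calibrated)
  mode <- if (forward == "fem-3d") "3d" else "2d"
  if (is.null(electrodes))
    electrodes <- default_electrodes(mode)
  if (is.null(area_mm2))
    area_mm2 <- electrodes$width_mm * electrodes$height_mm
  mesh <- if (forward != "surrogate")
    knee_mesh(stack, mode = mode, resolution = resolution,
              electrodes = electrodes)
  else NULL
  structure(list(profile = profile, tissues = tissues, forward = forward,
                 electrodes = electrodes, frequencies = frequencies,
                 area_mm2 = area_mm2, stack = stack, mesh = mesh),
            class = "knee_model")
}

#' @export
print.knee_model <- function(x, ...) {
  cat(sprintf("Personalized knee model (%s forward model)\n", x$forward))
  print(x$profile)
  print(x$stack)
  invisible(x)
}

#' Simulate the tetrapolar impedance spectrum of a knee model
#'
#' @param model A [knee_model()].
#' @param tissues Tissue table override (default: the model's own).
#' @param frequencies Frequency grid override.
#' @return An [impedance_spectrum()].
#' @export
simulate_spectrum <- function(model, tissues = model$tissues,
                              frequencies = model$frequencies) {
  if (!inherits(model, "knee_model"))
    stop_validation("'model' must be a knee_model")
  if (model$forward == "surrogate")
    analytic_layered_impedance(model$stack, tissues, model$area_mm2,
                               frequencies, muscle = "parallel")
  else
    fem_impedance_spectrum(model$mesh, knee_materials(tissues), frequencies)
}

#' @export
predict.knee_model <- function(object, frequencies = object$frequencies,
                               tissues = object$tissues, ...) {
  simulate_spectrum(object, tissues = tissues, frequencies = frequencies)
}
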