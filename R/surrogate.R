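#' One-dimensional layered-stack impedance
#'
#' Series combination of the five layers traversed by a uniform current tube
#' of cross-section `area_mm2`:
#' \deqn{Z(\omega) = \sum_i \frac{d_i}{\dot\sigma_i(\omega)\,A}}
#' with \eqn{\dot\sigma = j\omega\varepsilon_0\dot\varepsilon_{eff}} per
#' layer. This is both a fast mesh-free surrogate forward model for fitting
#' (hundreds of evaluations per personalization) and the analytic oracle for
#' layered finite-element tests. The muscle layer uses the parallel-fiber
#' parameter set by default: in a tetrapolar measurement the dominant muscle
#' path runs axially along the limb, i.e. along the fibers.
#'
#' @param stack A [layer_stack()] (thicknesses in mm). Layers with zero
#'   thickness are skipped with a warning.
#' @param tissue_table Tissue table supplying the dielectric parameters.
#' @param area_mm2 Cross-sectional area of the current tube in mm^2
#'   (default 400, a 20 x 20 mm electrode patch).
#' @param frequencies Frequencies in Hz.
#' @param muscle Which muscle row feeds layer 4: `"parallel"` (default) or
#'   `"transversal"`.
#' @return An [impedance_spectrum()] with complex impedances.
#' @export
analytic_layered_impedance <- function(stack, tissue_table = default_tissue_table(),
                                       area_mm2 = 400,
                                       frequencies = default_frequencies(),
                                       muscle = c("parallel", "transversal")) {
  muscle <- match.arg(muscle)
  if (!inherits(stack, "layer_stack"))
    stop_validation("'stack' must be a layer_stack")
  validate_tissue_table(tissue_table)
  assert_scalar_number(area_mm2, "area_mm2", lower = 0, strict_lower = TRUE)
  check_frequency(frequencies)
  tissues <- c(dry_skin = "Dry Skin", wet_skin = "Wet Skin", fat = "Fat",
               muscle = if (muscle == "parallel") "Muscle (Parallel)"
                        else "Muscle (Transversal)",
               bone = "Bone")
  A <- area_mm2 * 1e-6                      # m^2
  z <- complex(real = numeric(length(frequencies)))
  for (nm in names(tissues)) {
    d <- stack$thicknesses_mm[[nm]] * 1e-3  # m
    if (d == 0) { warning(sprintf("zero-thickness layer '%s' skipped", nm)); next }
    sig <- complex_conductivity(tissue_table[[tissues[[nm]]]], frequencies)
    z <- z + d / (sig * A)
  }
  impedance_spectrum(frequencies, z,
                     metadata = list(forward = "surrogate", muscle = muscle,
                                     area_mm2 = area_mm2))
}
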