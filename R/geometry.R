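## Per-sex geometric constants [mm]: dry-skin thickness (both sexes), wet-skin
## thickness and bone core radius, anchored to the reference thickness table.
LAYER1_MM <- 0.060
LAYER2_MM <- c(male = 4.501, female = 3.666)
LAYER5_MM <- c(male = 25.640, female = 22.760)

## BMI = 0.385 * SFT + 16.991, SFT in mm (sex-blind linear relation).
SFT_SLOPE <- 0.385
SFT_INTERCEPT <- 16.991
## Per-sex calibration = reference-table layer-3 thickness at BMI 23 divided
## by the raw linear value (15.192/15.608 and 16.971/15.608).
SFT_CALIBRATION <- c(male = 15.192, female = 16.971) / ((23 - 16.991) / 0.385)

#' Subject descriptors
#'
#' @param sex `"male"` or `"female"`.
#' @param bmi Body-mass index in kg/m^2, in `[10, 60]`.
#' @param circumferences_cm Three knee circumferences in cm, measured at the
#'   patella center, 5 cm above and 5 cm below; each in `[20, 80]`.
#' @param age Optional age in years.
#' @param kl_grade Optional Kellgren-Lawrence osteoarthritis grade (0-4).
#' @return An object of class `"subject_profile"`.
#' @export
subject_profile <- function(sex, bmi, circumferences_cm, age = NULL,
                            kl_grade = NULL) {
  sex <- match.arg(sex, c("male", "female"))
  assert_scalar_number(bmi, "bmi", lower = 10, upper = 60)
  if (!is.numeric(circumferences_cm) || length(circumferences_cm) != 3)
    stop_validation("'circumferences_cm' must be three lengths in cm")
  if (any(circumferences_cm < 20) || any(circumferences_cm > 80))
    stop_validation("each circumference must lie in [20, 80] cm")
  if (!is.null(kl_grade)) {
    assert_scalar_number(kl_grade, "kl_grade", lower = 0, upper = 4)
    kl_grade <- as.integer(kl_grade)
  }
  structure(list(sex = sex, bmi = bmi,
                 circumferences_cm = as.numeric(circumferences_cm),
                 age = age, kl_grade = kl_grade),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("Subject: %s, BMI %.1f kg/m^2, knee circumferences %s cm\n",
              x$sex, x$bmi, paste(sprintf("%.1f", x$circumferences_cm),
                                  collapse = "/")))
  invisible(x)
}

#' Mean knee radius
#'
#' The radius of the mean knee circumference: the three measurements are
#' averaged and divided by `2*pi`.
#'
#' @param circumferences_cm Three circumferences in cm.
#' @return Radius in mm.
#' @export
mean_radius <- function(circumferences_cm) {
  if (!is.numeric(circumferences_cm) || any(circumferences_cm <= 0))
    stop_validation("circumferences must be positive")
  mean(circumferences_cm) * 10 / (2 * pi)
}

#' Subcutaneous fat thickness from BMI
#'
#' Inverts the linear BMI relation `BMI = 0.385 * SFT + 16.991` (SFT in mm).
#' The linear relation is sex-blind; in the default calibrated mode the raw
#' value is multiplied by a per-sex factor chosen so that the reference case
#' (BMI 23) reproduces the anchored per-sex thicknesses (15.192 mm male,
#' 16.971 mm female).
#'
#' @param bmi Body-mass index in kg/m^2; must exceed the intercept 16.991 for
#'   a positive thickness.
#' @param sex `"male"` or `"female"` (ignored in raw mode).
#' @param calibrated Use the per-sex calibration (default) or the raw linear
#'   inversion.
#' @return Thickness of the subcutaneous fat layer in mm.
#' @export
subcutaneous_fat_thickness <- function(bmi, sex = c("male", "female"),
                                       calibrated = TRUE) {
  sex <- match.arg(sex)
  assert_scalar_number(bmi, "bmi")
  if (bmi <= SFT_INTERCEPT)
    stop_domain(sprintf(
      "BMI = %.3f is outside the domain of the linear SFT relation (BMI = 0.385*SFT + 16.991 requires BMI > 16.991)",
      bmi))
  raw <- (bmi - SFT_INTERCEPT) / SFT_SLOPE
  if (calibrated) raw * SFT_CALIBRATION[[sex]] else raw
}

#' Personalized five-layer thicknesses
#'
#' Computes the radial build-up of the five-layer knee model from a subject
#' profile: layer 1 (dry skin) is fixed at 60 um for both sexes; layers 2
#' (wet skin) and 5 (bone core radius) are per-sex constants; layer 3
#' (subcutaneous fat) follows the BMI relation; layer 4 (muscle) is the
#' residual so that the five values sum exactly to the mean radius.
#'
#' @param profile A [subject_profile()].
#' @param calibrated Passed to [subcutaneous_fat_thickness()].
#' @return An object of class `"layer_stack"`: named thicknesses in mm
#'   (`dry_skin`, `wet_skin`, `fat`, `muscle`, `bone`) plus `mean_radius_mm`
#'   and the subject's sex.
#' @export
personalize_thicknesses <- function(profile, calibrated = TRUE) {
  if (!inherits(profile, "subject_profile"))
    stop_validation("'profile' must be a subject_profile")
  r <- mean_radius(profile$circumferences_cm)
  l1 <- LAYER1_MM
  l2 <- LAYER2_MM[[profile$sex]]
  l5 <- LAYER5_MM[[profile$sex]]
  l3 <- subcutaneous_fat_thickness(profile$bmi, profile$sex, calibrated)
  l4 <- r - (l1 + l2 + l3 + l5)
  if (l4 <= 0)
    stop_domain(sprintf(
      "subject geometry infeasible: muscle layer residual %.3f mm <= 0 (mean radius %.3f mm, other layers %.3f mm)",
      l4, r, l1 + l2 + l3 + l5))
  structure(list(thicknesses_mm = c(dry_skin = l1, wet_skin = l2, fat = l3,
                                    muscle = l4, bone = l5),
                 mean_radius_mm = r, sex = profile$sex),
            class = "layer_stack")
}

#' Build a layer stack from explicit thicknesses
#'
#' Mostly for tests and what-if studies; [personalize_thicknesses()] is the
#' subject-driven constructor.
#'
#' @param dry_skin,wet_skin,fat,muscle,bone Thicknesses in mm (bone is the
#'   core radius), all > 0.
#' @return A `"layer_stack"` whose mean radius is the sum of the five values.
#' @export
layer_stack <- function(dry_skin, wet_skin, fat, muscle, bone) {
  th <- c(dry_skin = dry_skin, wet_skin = wet_skin, fat = fat,
          muscle = muscle, bone = bone)
  if (any(!is.finite(th)) || any(th <= 0))
    stop_validation("all five thicknesses must be positive")
  structure(list(thicknesses_mm = th, mean_radius_mm = sum(th), sex = NA),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("Five-layer knee stack (mean radius %.3f mm)\n",
              x$mean_radius_mm))
  lab <- c(dry_skin = "Layer 1 (dry skin)", wet_skin = "Layer 2 (wet skin)",
           fat = "Layer 3 (subcutaneous fat)", muscle = "Layer 4 (muscle)",
           bone = "Layer 5 (bone core radius)")
  for (nm in names(x$thicknesses_mm))
    cat(sprintf("  %-27s %8.3f mm\n", lab[[nm]], x$thicknesses_mm[[nm]]))
  invisible(x)
}

## Interface radii from the center outwards [mm]: bone core, then shells.
layer_radii <- function(stack) {
  th <- stack$thicknesses_mm
  cumsum(c(th[["bone"]], th[["muscle"]], th[["fat"]], th[["wet_skin"]],
           th[["dry_skin"]]))
}

## Tissue label of each radial layer, innermost first.
layer_tissues <- function() {
  c("Bone", "Muscle (Transversal)", "Fat", "Wet Skin", "Dry Skin")
}

#' Tetrapolar electrode configuration
#'
#' Four rectangular surface patches on the outer skin: a drive pair held at
#' opposite potentials and a sense pair drawing no current. Angles are in
#' degrees from the anterior midline; axial positions in mm from the patella
#' plane (z = 0 at mid-length of the modelled segment).
#'
#' @param theta_deg Angular positions of the four patches (drive+, drive-,
#'   sense+, sense-).
#' @param z_mm Axial positions of the patch centers.
#' @param width_mm Patch width along the circumference.
#' @param height_mm Patch height along the limb axis.
#' @return An object of class `"electrode_config"`.
#' @export
electrode_config <- function(theta_deg, z_mm = c(0, 0, 0, 0),
                             width_mm = 20, height_mm = 20) {
  if (length(theta_deg) != 4 || length(z_mm) != 4)
    stop_validation("four patches are required (drive+, drive-, sense+, sense-)")
  assert_scalar_number(width_mm, "width_mm", lower = 0, strict_lower = TRUE)
  assert_scalar_number(height_mm, "height_mm", lower = 0, strict_lower = TRUE)
  structure(list(theta = theta_deg * pi / 180, z_mm = as.numeric(z_mm),
                 width_mm = width_mm, height_mm = height_mm,
                 roles = c("drive+", "drive-", "sense+", "sense-")),
            class = "electrode_config")
}

#' Default electrode placement
#'
#' Drive patches 20 x 20 mm diametrically opposite at the patella plane
#' (medial/lateral, +-90 degrees). In 3D mode the sense patches sit at the same
#' angles, offset axially by 25 mm center-to-center (a 15 mm gap between patch
#' edges); in the 2D cross-sectional mode (no axial coordinate) the four
#' patches are spread in-plane, each sense patch 50 degrees from its drive
#' patch and off the drive pair's antisymmetry plane (where the potential
#' vanishes identically).
#'
#' @param mode `"3d"` or `"2d"`.
#' @return An [electrode_config()].
#' @export
default_electrodes <- function(mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  if (mode == "3d")
    electrode_config(theta_deg = c(90, -90, 90, -90),
                     z_mm = c(0, 0, 25, 25))
  else
    electrode_config(theta_deg = c(115, -115, 65, -65))
}
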