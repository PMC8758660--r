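#' Synthetic cohort specification
#'
#' Statistical structure of the validation cohort emulated by the generator:
#' 27% male, BMI 25 +- 4 kg/m^2, knee circumference 39 +- 4 cm, one third
#' affected by osteoarthritis, 3% multiplicative measurement noise.
#'
#' @param n_subjects Number of virtual subjects (>= 1).
#' @param male_fraction Probability of drawing a male subject.
#' @param bmi_mean,bmi_sd BMI distribution (truncated normal on `[10, 60]`).
#' @param circumference_mean,circumference_sd Knee circumference distribution
#'   in cm (truncated normal on `[20, 80]`); the three per-subject
#'   measurements jitter uniformly within +-1 cm of the subject mean.
#' @param osteoarthritis_fraction Fraction of subjects whose dielectric truth
#'   is drawn from the wider osteoarthritic range.
#' @param noise_sd Relative multiplicative noise on `|Z|`.
#' @param truth_range Log-uniform perturbation range of the seven default
#'   parameters for healthy subjects.
#' @param truth_range_oa Perturbation range for osteoarthritic subjects
#'   (wider; the pathology is assumed not to change the spectral trend, only
#'   the parameter spread).
#' @param seed RNG seed (every stochastic operation in the package takes an
#'   explicit seed; no global state is consumed).
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 30, male_fraction = 0.27,
                        bmi_mean = 25, bmi_sd = 4,
                        circumference_mean = 39, circumference_sd = 4,
                        osteoarthritis_fraction = 1 / 3,
                        noise_sd = 0.03,
                        truth_range = c(0.5, 2),
                        truth_range_oa = c(0.33, 3),
                        seed = 1) {
  assert_scalar_number(n_subjects, "n_subjects", lower = 1)
  assert_scalar_number(male_fraction, "male_fraction", lower = 0, upper = 1)
  assert_scalar_number(osteoarthritis_fraction, "osteoarthritis_fraction",
                       lower = 0, upper = 1)
  assert_scalar_number(bmi_sd, "bmi_sd", lower = 0)
  assert_scalar_number(circumference_sd, "circumference_sd", lower = 0)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 male_fraction = male_fraction,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 circumference_mean = circumference_mean,
                 circumference_sd = circumference_sd,
                 osteoarthritis_fraction = osteoarthritis_fraction,
                 noise_sd = noise_sd, truth_range = truth_range,
                 truth_range_oa = truth_range_oa, seed = as.integer(seed)),
            class = "cohort_spec")
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  for (k in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  stop_validation("truncated-normal rejection sampling failed")
}

#' Multiplicative measurement noise on a magnitude spectrum
#'
#' Each `|Z|` value is multiplied by an independent `1 + relative_sd * N(0,1)`
#' factor, floored at 10% of the clean value; frequencies are unchanged.
#'
#' @param spectrum An [impedance_spectrum()].
#' @param relative_sd Relative noise level (>= 0).
#' @param seed Explicit RNG seed.
#' @return A noisy [impedance_spectrum()] (magnitude-only output).
#' @export
add_measurement_noise <- function(spectrum, relative_sd, seed = 1) {
  if (!inherits(spectrum, "impedance_spectrum"))
    stop_validation("'spectrum' must be an impedance_spectrum")
  assert_scalar_number(relative_sd, "relative_sd", lower = 0)
  if (relative_sd == 0) {
    out <- impedance_spectrum(spectrum$frequency_hz, spectrum$magnitude,
                              metadata = spectrum$metadata)
    return(out)
  }
  n <- length(spectrum$magnitude)
  factors <- with_local_seed(seed, 1 + relative_sd * stats::rnorm(n))
  factors <- pmax(factors, 0.1)
  impedance_spectrum(spectrum$frequency_hz, spectrum$magnitude * factors,
                     metadata = c(spectrum$metadata,
                                  list(noise_sd = relative_sd,
                                       noise_seed = seed)))
}

#' Generate a synthetic validation cohort
#'
#' Draws virtual subjects (sex, BMI, knee circumferences), a dielectric truth
#' for each (independent log-uniform perturbations of the seven
#' personalization parameters, wider for osteoarthritic subjects, clipped to
#' the parameter bounds) and a noisy "measured" 13-point magnitude spectrum
#' produced by the layered surrogate forward model. Subjects whose geometry
#' is infeasible (muscle residual <= 0) are redrawn, at most 100 times each.
#' Fully reproducible from the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param tissues Baseline tissue table.
#' @param frequencies Measurement grid (default: 13 points, 1-49 kHz).
#' @return An object of class `"knee_cohort"`: a list of virtual subjects,
#'   each with `profile`, `truth`, `osteoarthritic`, `spectrum` (noisy) and
#'   `clean_spectrum`.
#' @export
generate_cohort <- function(spec, tissues = default_tissue_table(),
                            frequencies = default_frequencies()) {
  if (!inherits(spec, "cohort_spec"))
    stop_validation("'spec' must be a cohort_spec")
  base <- default_parameters(tissues)
  info <- personalization_parameter_info()
  subjects <- with_local_seed(spec$seed, {
    lapply(seq_len(spec$n_subjects), function(i) {
      profile <- NULL
      for (try in 1:100) {
        sex <- if (stats::runif(1) < spec$male_fraction) "male" else "female"
        bmi <- rtruncnorm1(spec$bmi_mean, spec$bmi_sd, 10, 60)
        circ0 <- rtruncnorm1(spec$circumference_mean, spec$circumference_sd,
                             21, 79)
        circs <- circ0 + stats::runif(3, -1, 1)
        oa <- stats::runif(1) < spec$osteoarthritis_fraction
        kl <- if (oa) sample(1:4, 1) else 0L
        cand <- subject_profile(sex, bmi, circs, kl_grade = kl)
        ok <- tryCatch({ personalize_thicknesses(cand); TRUE },
                       kneebis_domain_error = function(e) FALSE)
        if (ok) { profile <- cand; break }
      }
      if (is.null(profile))
        stop_validation(sprintf(
          "subject %d: no feasible geometry after 100 redraws", i))
      rng <- if (oa) spec$truth_range_oa else spec$truth_range
      fac <- exp(stats::runif(7, log(rng[1]), log(rng[2])))
      truth <- unclass(base) * fac
      is_alpha <- info$transform == "logit"
      truth[is_alpha] <- pmin(pmax(truth[is_alpha], ALPHA_LO), ALPHA_HI - 1e-6)
      truth <- validate_parameters(truth)
      noise_seed <- sample.int(.Machine$integer.max - 1L, 1)
      model <- knee_model(profile, apply_parameters(tissues, truth),
                          forward = "surrogate", frequencies = frequencies)
      clean <- simulate_spectrum(model)
      noisy <- add_measurement_noise(clean, spec$noise_sd, seed = noise_seed)
      noisy$metadata$subject_id <- i
      structure(list(id = i, profile = profile, truth = truth,
                     osteoarthritic = oa, spectrum = noisy,
                     clean_spectrum = clean, noise_seed = noise_seed),
                class = "virtual_subject")
    })
  })
  structure(list(subjects = subjects, spec = spec), class = "knee_cohort")
}

#' @export
print.knee_cohort <- function(x, ...) {
  sexes <- vapply(x$subjects, function(s) s$profile$sex, character(1))
  cat(sprintf("Synthetic knee cohort: %d subjects (%.0f%% male, %.0f%% osteoarthritic)\n",
              length(x$subjects), 100 * mean(sexes == "male"),
              100 * mean(vapply(x$subjects, `[[`, logical(1),
                                "osteoarthritic"))))
  invisible(x)
}

#' Export a cohort to CSV spectra plus a JSON manifest
#'
#' Writes one magnitude-spectrum CSV per subject and a `manifest.json`
#' carrying profiles, truths and seeds, so a cohort can be re-analysed
#' without regenerating it.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "knee_cohort"))
    stop_validation("'cohort' must be a knee_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(cohort$subjects, function(s) {
    file <- sprintf("subject_%03d.csv", s$id)
    write_spectrum_csv(s$spectrum, file.path(dir, file),
                       metadata = sprintf("synthetic subject %d (%s)", s$id,
                                          s$profile$sex))
    list(id = s$id, file = file, sex = s$profile$sex, bmi = s$profile$bmi,
         circumferences_cm = s$profile$circumferences_cm,
         kl_grade = s$profile$kl_grade,
         osteoarthritic = s$osteoarthritic,
         truth = as.list(unclass(s$truth)), noise_seed = s$noise_seed)
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(seed = cohort$spec$seed,
                            noise_sd = cohort$spec$noise_sd,
                            subjects = manifest),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Synthetic reference muscle spectra
#'
#' Evaluates the real permittivity and equivalent conductivity of a known
#' parameter set on a frequency grid (optionally with relative noise),
#' producing the synthetic stand-in for the literature parallel-muscle
#' measurements that the identification step fits.
#'
#' @param truth A [cole_cole()] parameter set.
#' @param frequency_grid Grid in Hz (default: 48 log-spaced points,
#'   1 Hz - 1 GHz).
#' @param noise_sd Relative noise on both channels (0 = exact).
#' @param seed RNG seed when `noise_sd > 0`.
#' @return A [reference_spectrum()] tagged synthetic.
#' @export
generate_reference_muscle_spectra <- function(truth,
                                              frequency_grid =
                                                10^seq(0, 9, length.out = 48),
                                              noise_sd = 0, seed = 1) {
  if (!inherits(truth, "cole_cole"))
    stop_validation("'truth' must be a cole_cole object")
  eps <- Re(effective_permittivity(truth, frequency_grid))
  sig <- equivalent_conductivity(truth, frequency_grid)
  if (noise_sd > 0) {
    n <- length(frequency_grid)
    f <- with_local_seed(seed, 1 + noise_sd * stats::rnorm(2 * n))
    eps <- eps * pmax(f[seq_len(n)], 0.1)
    sig <- sig * pmax(f[n + seq_len(n)], 0.1)
  }
  reference_spectrum(frequency_grid, eps, sig, provenance = "synthetic")
}
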