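#' Cole-Cole dispersion term
#'
#' One relaxation process of a multi-dispersion Cole-Cole model: a permittivity
#' increment `delta_eps` relaxing with characteristic time `tau` and spectral
#' broadening exponent `alpha` (`alpha = 0` reduces to Debye relaxation).
#'
#' @param delta_eps Dimensionless (relative) permittivity increment, >= 0.
#' @param tau Relaxation time in seconds, > 0.
#' @param alpha Broadening exponent in `[0, 1)`.
#' @return An object of class `"dispersion"`.
#' @export
dispersion <- function(delta_eps, tau, alpha = 0) {
  assert_scalar_number(delta_eps, "delta_eps", lower = 0)
  assert_scalar_number(tau, "tau", lower = 0, strict_lower = TRUE)
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1 - 1e-12)
  structure(list(delta_eps = delta_eps, tau = tau, alpha = alpha),
            class = "dispersion")
}

#' Cole-Cole parameter set for one tissue
#'
#' Parameters of the effective dielectric permittivity
#' \deqn{\dot\varepsilon_{eff}(\omega) = \varepsilon_\infty +
#'   \sum_n \frac{\Delta\varepsilon_n}{1 + (j\omega\tau_n)^{1-\alpha_n}} +
#'   \frac{\sigma_{dc}}{j\omega\varepsilon_0}}
#' under the \eqn{e^{+j\omega t}} time convention, so the conduction term
#' contributes negative imaginary permittivity.
#'
#' @param eps_inf High-frequency relative permittivity, >= 1.
#' @param dispersions List of [dispersion()] objects (possibly empty; at most
#'   four in the packaged tissue table).
#' @param sigma_dc Static conductivity in S/m, >= 0.
#' @param label Optional tissue label.
#' @return An object of class `"cole_cole"`.
#' @export
cole_cole <- function(eps_inf, dispersions = list(), sigma_dc = 0, label = NULL) {
  assert_scalar_number(eps_inf, "eps_inf", lower = 1)
  assert_scalar_number(sigma_dc, "sigma_dc", lower = 0)
  if (!is.list(dispersions))
    stop_validation("'dispersions' must be a list of dispersion() objects")
  dispersions <- lapply(dispersions, function(d) {
    if (inherits(d, "dispersion")) d
    else do.call(dispersion, as.list(d)[c("delta_eps", "tau", "alpha")])
  })
  structure(list(eps_inf = eps_inf, dispersions = dispersions,
                 sigma_dc = sigma_dc, label = label),
            class = "cole_cole")
}

#' @export
print.cole_cole <- function(x, ...) {
  cat(sprintf("Cole-Cole tissue model%s\n",
              if (!is.null(x$label)) paste0(": ", x$label) else ""))
  cat(sprintf("  eps_inf  = %g\n  sigma_dc = %g S/m\n", x$eps_inf, x$sigma_dc))
  for (i in seq_along(x$dispersions)) {
    d <- x$dispersions[[i]]
    cat(sprintf("  n=%d: delta_eps = %g, tau = %g s, alpha = %g\n",
                i, d$delta_eps, d$tau, d$alpha))
  }
  invisible(x)
}

check_frequency <- function(frequency) {
  if (!is.numeric(frequency) || any(!is.finite(frequency)) || any(frequency <= 0))
    stop_domain("'frequency' must be positive and finite (Hz)")
  invisible(frequency)
}

#' Complex effective relative permittivity
#'
#' Evaluates the multi-dispersion Cole-Cole effective dielectric permittivity
#' (polarization plus ohmic conduction) at the given frequencies. Under the
#' adopted \eqn{e^{+j\omega t}} convention the imaginary part is <= 0 for any
#' valid parameter set.
#'
#' @param params A [cole_cole()] object.
#' @param frequency Frequency in Hz (vectorized), > 0.
#' @return Complex vector of relative permittivities.
#' @export
effective_permittivity <- function(params, frequency) {
  if (!inherits(params, "cole_cole"))
    stop_validation("'params' must be a cole_cole object")
  check_frequency(frequency)
  w <- 2 * pi * frequency
  eps <- complex(real = rep(params$eps_inf, length(w)), imaginary = 0)
  for (d in params$dispersions)
    eps <- eps + d$delta_eps / (1 + (1i * w * d$tau)^(1 - d$alpha))
  eps + params$sigma_dc / (1i * w * EPS0)
}

#' Equivalent conductivity
#'
#' \eqn{\sigma_{eq}(\omega) = -\omega\varepsilon_0\,\mathrm{Im}\,
#' \dot\varepsilon_{eff}(\omega)}: the dissipative part of the effective
#' permittivity expressed as a conductivity. Converges to `sigma_dc` as
#' frequency tends to zero and is non-decreasing in frequency.
#'
#' @inheritParams effective_permittivity
#' @return Numeric vector in S/m.
#' @export
equivalent_conductivity <- function(params, frequency) {
  eps <- effective_permittivity(params, frequency)
  2 * pi * frequency * EPS0 * (-Im(eps))
}

#' Complex conductivity of a tissue
#'
#' \eqn{\dot\sigma = j\omega\varepsilon_0\dot\varepsilon_{eff}}: the single
#' material coefficient of the quasi-static potential problem, whose real part
#' is the equivalent conductivity and whose imaginary part carries the
#' displacement (capacitive) current.
#'
#' @inheritParams effective_permittivity
#' @return Complex vector in S/m.
#' @export
complex_conductivity <- function(params, frequency) {
  1i * 2 * pi * frequency * EPS0 * effective_permittivity(params, frequency)
}

#' Anisotropic muscle permittivity
#'
#' Skeletal muscle responds differently to electric fields along and across
#' its fibers. The scalar Cole-Cole permittivity becomes a diagonal tensor in
#' the fiber-aligned frame, with the parallel parameter set on the fiber axis
#' and the perpendicular set on the two orthogonal axes.
#'
#' @param parallel [cole_cole()] parameters for excitation along the fibers.
#' @param perpendicular [cole_cole()] parameters for excitation across the
#'   fibers.
#' @param fiber_axis Unit 3-vector giving the fiber direction; defaults to the
#'   limb's longitudinal axis (z).
#' @return An object of class `"anisotropic_permittivity"`.
#' @export
anisotropic_permittivity <- function(parallel, perpendicular,
                                     fiber_axis = c(0, 0, 1)) {
  if (!inherits(parallel, "cole_cole") || !inherits(perpendicular, "cole_cole"))
    stop_validation("'parallel' and 'perpendicular' must be cole_cole objects")
  if (!is.numeric(fiber_axis) || length(fiber_axis) != 3 ||
      abs(sqrt(sum(fiber_axis^2)) - 1) > 1e-8)
    stop_validation("'fiber_axis' must be a unit 3-vector")
  structure(list(parallel = parallel, perpendicular = perpendicular,
                 fiber_axis = as.numeric(fiber_axis)),
            class = "anisotropic_permittivity")
}

#' Muscle permittivity tensor at one frequency
#'
#' @param aniso An [anisotropic_permittivity()] object.
#' @param frequency Frequency in Hz (scalar).
#' @return A symmetric 3x3 complex matrix whose eigenvalue on the fiber axis is
#'   the parallel effective permittivity and whose other two eigenvalues equal
#'   the perpendicular one.
#' @export
muscle_tensor <- function(aniso, frequency) {
  if (!inherits(aniso, "anisotropic_permittivity"))
    stop_validation("'aniso' must be an anisotropic_permittivity object")
  assert_scalar_number(frequency, "frequency", lower = 0, strict_lower = TRUE)
  e_par <- effective_permittivity(aniso$parallel, frequency)
  e_perp <- effective_permittivity(aniso$perpendicular, frequency)
  a <- aniso$fiber_axis
  e_perp * diag(3) + (e_par - e_perp) * (a %o% a)
}
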