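tab <- default_tissue_table()
anchor <- tab[["Muscle (Transversal)"]]

scaled_recovery_error <- function(result, truth) {
  ts <- kneebis:::cc_to_scaled(truth)
  abs(result$scaled_L - ts) / pmax(1, abs(ts))
}

test_that("spectrum misfit matches its arithmetic definition", {
  truth <- tab[["Muscle (Parallel)"]]
  ref <- generate_reference_muscle_spectra(truth)
  expect_equal(spectrum_misfit(truth, ref), 0, tolerance = 1e-12)

  # uniform 10% offset in both channels scores exactly 0.10
  ref_off <- reference_spectrum(ref$frequency_hz, ref$eps_real / 1.10,
                                ref$sigma_eq / 1.10)
  expect_equal(spectrum_misfit(truth, ref_off), 0.10, tolerance = 1e-12)

  # random candidate vs the hand-coded two-channel oracle
  cand <- tab[["Bone"]]
  a <- cc_as_args(cand)
  eps_m <- vapply(ref$frequency_hz, function(f)
    Re(do.call(oracle_eps, c(a, list(f = f)))), numeric(1))
  sig_m <- vapply(ref$frequency_hz, function(f)
    do.call(oracle_sigma_eq, c(a, list(f = f))), numeric(1))
  hand <- sqrt((mean(((eps_m - ref$eps_real) / ref$eps_real)^2) +
                  mean(((sig_m - ref$sigma_eq) / ref$sigma_eq)^2)) / 2)
  expect_equal(spectrum_misfit(cand, ref), hand, tolerance = 1e-12)

  # channel/grid length mismatches are rejected at construction
  expect_error(reference_spectrum(c(1, 2, 3), c(1, 1), c(1, 1, 1)),
               class = "kneebis_validation_error")
})

test_that("a reference generated from the anchor is returned unchanged", {
  ref <- generate_reference_muscle_spectra(anchor)
  res <- identify_parallel_parameters(ref, anchor)
  expect_true(res$feasible)
  expect_equal(res$distance, 0, tolerance = 1e-8)
  expect_lt(res$fit_residual, 1e-10)
})

test_that("a tau4/sigma_dc-perturbed truth is recovered from noise-free spectra", {
  truth <- anchor
  truth$dispersions[[4]]$tau <- truth$dispersions[[4]]$tau * 2
  truth$sigma_dc <- truth$sigma_dc * 2
  ref <- generate_reference_muscle_spectra(truth)
  res <- identify_parallel_parameters(ref, anchor)
  expect_true(res$feasible)
  expect_true(all(scaled_recovery_error(res, truth) < 0.05))
})

test_that("loosening the constraint tolerance never increases the distance", {
  truth <- tab[["Muscle (Parallel)"]]
  ref <- generate_reference_muscle_spectra(truth)
  d <- vapply(c(1e-3, 1e-2, 1e-1), function(tol)
    identify_parallel_parameters(ref, anchor, constraint_tolerance = tol)$distance,
    numeric(1))
  expect_true(all(diff(d) <= 1e-6))
})

test_that("random in-band perturbed truths are recovered noise-free", {
  # dispersions 3-4 and sigma_dc dominate the identification band; tau1-scale
  # parameters are asserted only against the anchor-sized tolerance
  set.seed(5)
  in_band <- c("sigma_dc", "delta_eps3", "tau3", "alpha3", "delta_eps4",
               "tau4", "eps_inf")
  for (k in 1:6) {
    truth <- anchor
    truth$sigma_dc <- truth$sigma_dc * 10^runif(1, -0.3, 0.3)
    for (i in 3:4) {
      truth$dispersions[[i]]$delta_eps <-
        truth$dispersions[[i]]$delta_eps * 10^runif(1, -0.3, 0.3)
      truth$dispersions[[i]]$tau <-
        truth$dispersions[[i]]$tau * 10^runif(1, -0.3, 0.3)
      truth$dispersions[[i]]$alpha <- runif(1, 0, 0.35)
    }
    ref <- generate_reference_muscle_spectra(truth)
    res <- identify_parallel_parameters(ref, anchor)
    expect_lt(res$fit_residual, 1e-3)
    err <- scaled_recovery_error(res, truth)
    expect_true(all(err[in_band] < 0.05),
                info = paste("draw", k, ":",
                             paste(names(err[in_band]), round(err[in_band], 4),
                                   collapse = " ")))
  }
})

test_that("among equally good fits the solution closer to the anchor wins", {
  # two dispersions sharing tau and alpha: only the sum of their increments
  # is observable, so the feasible set is a ridge
  shared <- list(tau = 1e-4, alpha = 0.1)
  anchor2 <- cole_cole(4, list(dispersion(1e4, shared$tau, shared$alpha),
                               dispersion(3e4, shared$tau, shared$alpha)),
                       0.2)
  truth2 <- cole_cole(4, list(dispersion(2e4, shared$tau, shared$alpha),
                              dispersion(2e4, shared$tau, shared$alpha)),
                      0.2)
  ref <- generate_reference_muscle_spectra(truth2)
  res <- identify_parallel_parameters(ref, anchor2)
  expect_true(res$feasible)
  # the mirrored split fits equally well but lies farther from the anchor
  mirrored <- res$scaled_L
  mirrored[c("delta_eps1", "delta_eps2")] <- mirrored[c("delta_eps2", "delta_eps1")]
  d_mirror <- sqrt(sum((mirrored - res$scaled_P)^2))
  expect_lte(res$distance, d_mirror + 1e-8)
  # and the returned increments keep the anchor's ordering (disp2 > disp1)
  expect_gt(res$scaled_L[["delta_eps2"]], res$scaled_L[["delta_eps1"]])
})

test_that("degenerate references and short grids are rejected", {
  expect_error(identify_parallel_parameters(
    reference_spectrum(1:20, rep(5, 20), rep(0.1, 20)), anchor),
    regexp = "degenerate", class = "kneebis_validation_error")
  short <- generate_reference_muscle_spectra(anchor,
                                             frequency_grid = 10^seq(1, 3, length.out = 5))
  expect_error(identify_parallel_parameters(short, anchor),
               class = "kneebis_validation_error")
})
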