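tab <- default_tissue_table()
profile <- reference_profile("male")
info <- kneebis:::personalization_parameter_info()

perturbed_truth <- function(factor) {
  th <- unclass(default_parameters(tab)) * factor
  th[info$transform == "logit"] <- pmin(th[info$transform == "logit"], 0.94)
  kneebis:::validate_parameters(th)
}

measured_from <- function(truth, noise = 0, seed = 1) {
  m <- knee_model(profile, apply_parameters(tab, truth), forward = "surrogate")
  sp <- simulate_spectrum(m)
  if (noise > 0) sp <- add_measurement_noise(sp, noise, seed = seed)
  sp
}

test_that("reconstruction error is the relative L2 magnitude distance", {
  f <- default_frequencies()
  set.seed(2)
  a <- impedance_spectrum(f, runif(13, 100, 300))
  b <- impedance_spectrum(f, runif(13, 100, 300))
  expect_equal(reconstruction_error(a, a), 0)
  expect_equal(reconstruction_error(a,
                                    impedance_spectrum(f, 1.03 * a$magnitude)),
               0.03, tolerance = 1e-12)
  hand <- sqrt(sum((a$magnitude - b$magnitude)^2)) / sqrt(sum(a$magnitude^2))
  expect_equal(reconstruction_error(a, b), hand, tolerance = 1e-14)
  # scale awareness: common rescaling cancels, one-sided scaling is exact
  expect_equal(reconstruction_error(impedance_spectrum(f, 7 * a$magnitude),
                                    impedance_spectrum(f, 7 * b$magnitude)),
               hand, tolerance = 1e-12)
  expect_error(reconstruction_error(a, impedance_spectrum(f * 2, a$magnitude)),
               class = "kneebis_validation_error")
})

test_that("sensitivity analysis scores and ranks parameters sensibly", {
  model <- knee_model(profile, tab, forward = "surrogate")
  rep_all <- sensitivity_analysis(model)
  expect_s3_class(rep_all, "sensitivity_report")
  expect_true(all(rep_all$score >= 0))
  expect_identical(sort(rep_all$rank), seq_len(nrow(rep_all)))
  # ~80 probed parameters: 6 tissues, eps_inf + sigma_dc + 3 per dispersion
  expect_gte(nrow(rep_all), 70)

  # a null (zero-valued) parameter scores exactly zero under a relative step
  tab0 <- tab
  tab0[["Bone"]]$dispersions[[1]]$delta_eps <- 0
  r0 <- sensitivity_analysis(knee_model(profile, tab0),
                             parameters = "Bone.delta_eps1")
  expect_identical(r0$score, 0)

  # raising a conductivity moves the low-frequency magnitude
  r_sig <- sensitivity_analysis(model, parameters = "Fat.sigma_dc")
  expect_gt(r_sig$score, 0)

  # the seven personalization parameters all carry measurable sensitivity
  probe <- c("Wet Skin.delta_eps3", "Wet Skin.delta_eps4", "Fat.alpha4",
             "Fat.sigma_dc", "Muscle (Parallel).alpha3",
             "Muscle (Parallel).tau4", "Muscle (Parallel).sigma_dc")
  r7 <- sensitivity_analysis(model, parameters = probe)
  expect_true(all(r7$score > 0))

  # reported (not asserted): how many of the full probe's top seven coincide
  # with the personalization set
  overlap <- length(intersect(rep_all$name[1:7], probe))
  cat(sprintf("\n  top-7 sensitivity overlap with the personalization set: %d/7\n",
              overlap))
})

test_that("fitting a spectrum generated at the defaults is a fixed point", {
  measured <- measured_from(default_parameters(tab))
  fit <- personalize(measured, profile)
  expect_lt(fit$eps_fit, 1e-4)
  expect_equal(unclass(fit$parameters), unclass(default_parameters(tab)),
               tolerance = 1e-6)
})

test_that("all seven parameters perturbed x1.2 are recovered noise-free", {
  truth <- perturbed_truth(1.2)
  fit <- personalize(measured_from(truth), profile)
  expect_lt(fit$eps_fit, 1e-3)
  tt <- kneebis:::to_transformed(truth)
  th <- kneebis:::to_transformed(fit$parameters)
  expect_true(all(abs(th - tt) / pmax(1, abs(tt)) < 0.05))
})

test_that("fitting never increases the error and is bit-deterministic", {
  measured <- measured_from(perturbed_truth(1.4), noise = 0.05, seed = 9)
  f1 <- personalize(measured, profile)
  f2 <- personalize(measured, profile)
  expect_lte(f1$eps_fit, f1$initial_error)
  expect_identical(unclass(f1$parameters), unclass(f2$parameters))
  expect_identical(f1$eps_fit, f2$eps_fit)
})

test_that("recovery degrades gracefully with measurement noise", {
  set.seed(31)
  mean_err <- vapply(c(0, 0.03, 0.10), function(noise) {
    errs <- vapply(1:10, function(k) {
      truth <- kneebis:::validate_parameters(
        unclass(default_parameters(tab)) *
          exp(runif(7, log(0.7), log(1.4))))
      fit <- personalize(measured_from(truth, noise = noise, seed = 100 + k),
                         profile)
      tt <- kneebis:::to_transformed(truth)
      th <- kneebis:::to_transformed(fit$parameters)
      mean(abs(th - tt) / pmax(1, abs(tt)))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(mean_err[1], mean_err[2])
  expect_lt(mean_err[2], mean_err[3])
})

test_that("the fitted object supports the standard modelling verbs", {
  measured <- measured_from(perturbed_truth(1.1), noise = 0.03, seed = 4)
  fit <- personalize(measured, profile)
  expect_named(coef(fit), info$name)
  expect_s3_class(fitted(fit), "impedance_spectrum")
  expect_length(residuals(fit), 13)
  expect_equal(unname(residuals(fit, "absolute")),
               measured$magnitude - fitted(fit)$magnitude)
  s <- summary(fit)
  expect_s3_class(s, "summary.knee_fit")
  expect_output(print(s), "parameter movement")
  pr <- predict(fit, frequencies = c(2e3, 5e3, 2e4))
  expect_length(pr$magnitude, 3)
  sims <- simulate(fit, nsim = 2, seed = 7)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$magnitude, sims[[2]]$magnitude))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
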