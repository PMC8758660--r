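test_that("dispersion-free and Debye closed forms are reproduced", {
  flat <- cole_cole(4, list(), 0)
  expect_equal(effective_permittivity(flat, 1234), 4 + 0i)
  expect_equal(equivalent_conductivity(cole_cole(4, list(), 0.5), 777), 0.5)

  # Debye term at w*tau = 1: eps = eps_inf + d_eps*(1-1i)/2
  tau <- 1e-5
  f <- 1 / (2 * pi * tau)
  deb <- cole_cole(4, list(dispersion(100, tau, 0)), 0)
  expect_equal(effective_permittivity(deb, f), complex(real = 54, imaginary = -50),
               tolerance = 1e-12)
})

test_that("effective permittivity matches the direct-formula oracle", {
  tab <- default_tissue_table()
  for (tissue in c("Dry Skin", "Wet Skin", "Muscle (Transversal)")) {
    a <- cc_as_args(tab[[tissue]])
    for (f in c(1e4, 49e3, 1e6)) {
      expect_equal(effective_permittivity(tab[[tissue]], f),
                   do.call(oracle_eps, c(a, list(f = f))), tolerance = 1e-13)
    }
  }
  a <- cc_as_args(tab[["Muscle (Transversal)"]])
  expect_equal(equivalent_conductivity(tab[["Muscle (Transversal)"]], 49e3),
               do.call(oracle_sigma_eq, c(a, list(f = 49e3))),
               tolerance = 1e-13)
})

test_that("equivalent conductivity tends to sigma_dc at low frequency", {
  set.seed(11)
  for (k in 1:10) {
    p <- random_cole_cole()
    expect_equal(equivalent_conductivity(p, 1e-3), p$sigma_dc,
                 tolerance = 1e-3)
  }
})

test_that("invalid parameters and frequencies are rejected", {
  expect_error(dispersion(-1, 1e-6, 0), class = "kneebis_validation_error")
  expect_error(dispersion(10, 0, 0), class = "kneebis_validation_error")
  expect_error(dispersion(10, 1e-6, 1), class = "kneebis_validation_error")
  expect_error(cole_cole(0.5, list(), 0), class = "kneebis_validation_error")
  expect_error(effective_permittivity(cole_cole(4, list(), 0), -5),
               class = "kneebis_domain_error")
})

test_that("permittivity real part decreases and conductivity increases with frequency", {
  set.seed(7)
  freqs <- 10^seq(0, 9, length.out = 60)
  for (k in 1:20) {
    p <- random_cole_cole()
    eps <- effective_permittivity(p, freqs)
    expect_true(all(Im(eps) <= 1e-12))
    expect_true(all(diff(Re(eps)) <= 1e-8 * abs(Re(eps))[-1]))
    sig <- equivalent_conductivity(p, freqs)
    expect_true(all(diff(sig) >= -1e-10 * sig[-1]))
  }
})

test_that("alpha = 0 collapses to a sum of Debye relaxations", {
  set.seed(23)
  freqs <- 10^seq(1, 8, length.out = 25)
  for (k in 1:10) {
    nd <- sample(1:4, 1)
    d_eps <- 10^runif(nd, 0, 6); tau <- 10^runif(nd, -10, -3)
    sig <- runif(1, 0, 0.3)
    p <- cole_cole(5, lapply(seq_len(nd), function(i)
      dispersion(d_eps[i], tau[i], 0)), sig)
    expect_equal(effective_permittivity(p, freqs),
                 vapply(freqs, function(f) oracle_debye(5, d_eps, tau, sig, f),
                        complex(1)),
                 tolerance = 1e-12)
  }
})

test_that("muscle tensor is diagonal in the fiber frame and rotates correctly", {
  tab <- default_tissue_table()
  aniso <- default_muscle_anisotropy(tab)
  f <- 1e4
  e_par <- effective_permittivity(tab[["Muscle (Parallel)"]], f)
  e_perp <- effective_permittivity(tab[["Muscle (Transversal)"]], f)
  expect_equal(muscle_tensor(aniso, f), diag(c(e_perp, e_perp, e_par)))

  iso <- anisotropic_permittivity(tab[["Bone"]], tab[["Bone"]],
                                  fiber_axis = c(1, 2, 2) / 3)
  e_b <- effective_permittivity(tab[["Bone"]], f)
  expect_equal(muscle_tensor(iso, f), e_b * diag(3), tolerance = 1e-12)

  # rotation oracle: R diag(e_perp, e_perp, e_par) R^T for fibers along x
  ax <- anisotropic_permittivity(tab[["Muscle (Parallel)"]],
                                 tab[["Muscle (Transversal)"]],
                                 fiber_axis = c(1, 0, 0))
  R <- matrix(c(0, 0, 1, 0, 1, 0, -1, 0, 0), 3, 3)  # maps z-axis onto x-axis
  expect_equal(muscle_tensor(ax, f),
               R %*% diag(c(e_perp, e_perp, e_par)) %*% t(R),
               tolerance = 1e-12)
  expect_error(anisotropic_permittivity(tab[["Bone"]], tab[["Bone"]],
                                        fiber_axis = c(1, 1, 0)),
               class = "kneebis_validation_error")
})

test_that("the packaged tissue table carries the reference constants", {
  tab <- default_tissue_table()
  expect_setequal(names(tab),
                  c("Dry Skin", "Wet Skin", "Fat", "Muscle (Transversal)",
                    "Muscle (Parallel)", "Bone"))
  expect_identical(tab[["Muscle (Parallel)"]]$sigma_dc, 0.2397)
  expect_identical(tab[["Muscle (Parallel)"]]$dispersions[[4]]$tau, 0.737e-3)
  expect_identical(tab[["Fat"]]$sigma_dc, 0.0350)
  expect_length(tab[["Dry Skin"]]$dispersions, 2)
  expect_length(tab[["Wet Skin"]]$dispersions, 4)
})

test_that("tissue tables round-trip through YAML", {
  tab <- default_tissue_table()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_tissue_table(tab, path)
  back <- read_tissue_table(path)
  expect_identical(names(back), names(tab))
  for (nm in names(tab)) {
    expect_equal(back[[nm]]$eps_inf, tab[[nm]]$eps_inf)
    expect_equal(back[[nm]]$sigma_dc, tab[[nm]]$sigma_dc)
    expect_equal(lapply(back[[nm]]$dispersions, unclass),
                 lapply(tab[[nm]]$dispersions, unclass), tolerance = 1e-12)
  }
})
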