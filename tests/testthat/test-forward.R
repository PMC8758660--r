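# Solver correctness is property-based: closed forms, conservation laws and
# symmetries stand in for unavailable reference field solutions.

knee2d <- knee_mesh(personalize_thicknesses(reference_profile("male")),
                    "2d", resolution = 1)
knee_mat <- knee_materials()

test_that("homogeneous cylinder with end-cap terminals is Ohm's law", {
  stack <- layer_stack(1, 1, 1, 10, 12)   # radius 25 mm
  mesh <- knee_mesh(stack, "3d", resolution = 1, electrodes = NULL,
                    axial_length_mm = 50)
  sigma <- 0.5
  bnd <- boundary_spec(list(list(nodes = mesh$cap_nodes$bottom, value = 0.5),
                            list(nodes = mesh$cap_nodes$top, value = -0.5)))
  field <- solve_potential(mesh, uniform_materials(sigma), bnd, 1e4)
  z <- 1 / terminal_current(field, 1)
  z_ref <- 0.05 / (sigma * pi * 0.025^2)
  expect_lt(Mod(z - z_ref) / z_ref, 0.01)
  expect_lt(abs(Im(z)) / Mod(z), 1e-10)

  # charge conservation and the volume power-balance oracle
  i1 <- terminal_current(field, 1); i2 <- terminal_current(field, 2)
  expect_lt(Mod(i1 + i2) / Mod(i1), 1e-8)
  power <- kneebis:::element_power(mesh, field, uniform_materials(sigma), 1e4)
  expect_equal(Conj(0.5) * i1 + Conj(-0.5) * i2, power, tolerance = 1e-9)
})

test_that("axial two-layer stack matches the series-impedance oracle", {
  stack <- layer_stack(1, 1, 1, 10, 12)
  mesh <- knee_mesh(stack, "3d", resolution = 1, electrodes = NULL,
                    axial_length_mm = 50)
  mesh$region <- ifelse(mesh$centroid[, 3] < 0, 1L, 2L)
  mesh$region_names <- c("lower", "upper")
  s1 <- 0.3 + 0i; s2 <- 0.8 + 0.2i
  mats <- function(region, frequency)
    if (region == "lower") c(t = s1, z = s1) else c(t = s2, z = s2)
  bnd <- boundary_spec(list(list(nodes = mesh$cap_nodes$bottom, value = 0.5),
                            list(nodes = mesh$cap_nodes$top, value = -0.5)))
  field <- solve_potential(mesh, mats, bnd, 1e4)
  z <- 1 / terminal_current(field, 1)
  area <- pi * 0.025^2
  z_ref <- 0.025 / (s1 * area) + 0.025 / (s2 * area)
  expect_lt(Mod(z - z_ref) / Mod(z_ref), 0.01)
})

test_that("scaling all material coefficients scales impedance inversely", {
  k <- 2.5 - 1.2i
  z1 <- tetrapolar_impedance(knee2d, knee_mat, 1e4)
  mat_k <- function(region, frequency) knee_mat(region, frequency) * k
  z2 <- tetrapolar_impedance(knee2d, mat_k, 1e4)
  expect_equal(z2, z1 / k, tolerance = 1e-10)
})

test_that("tetrapolar impedance is reciprocal under drive/sense exchange", {
  stack <- personalize_thicknesses(reference_profile("male"))
  set.seed(19)
  for (k in 1:5) {
    th <- c(45, 135, 225, 315) + runif(4, -20, 20)
    perm <- c(sample(1:2), sample(3:4))
    th <- th[c(perm[1], perm[2], perm[3], perm[4])]
    m1 <- knee_mesh(stack, "2d", 1, electrodes = electrode_config(th))
    m2 <- knee_mesh(stack, "2d", 1,
                    electrodes = electrode_config(th[c(3, 4, 1, 2)]))
    z1 <- tetrapolar_impedance(m1, knee_mat, 1e4)
    z2 <- tetrapolar_impedance(m2, knee_mat, 1e4)
    expect_lt(Mod(z1 - z2) / Mod(z1), 1e-4)
  }
})

test_that("sense patches on the drive patches reduce to the bipolar reading", {
  stack <- personalize_thicknesses(reference_profile("male"))
  mesh <- knee_mesh(stack, "2d", 1,
                    electrodes = electrode_config(c(90, -90, 90, -90)))
  z_tetra <- tetrapolar_impedance(mesh, knee_mat, 1e4)
  z_bi <- tetrapolar_impedance(mesh, knee_mat, 1e4, bipolar = TRUE)
  expect_equal(z_tetra, z_bi)
})

test_that("impedance has positive real part and |Z| falls at low frequency", {
  sp <- fem_impedance_spectrum(knee2d, knee_mat,
                               frequencies = default_frequencies(13))
  expect_true(all(Re(sp$z) > 0))
  # tissue dispersion makes |Z| fall through the lower half of the band; the
  # tetrapolar transfer impedance may rise again near the top of the band as
  # displacement currents reroute the current paths
  expect_true(all(diff(sp$magnitude[1:8]) < 0))
  # conductivity-only materials give a flat, purely real spectrum
  flat <- fem_impedance_spectrum(knee2d, uniform_materials(0.25),
                                 frequencies = default_frequencies(3))
  expect_lt(diff(range(flat$magnitude)) / flat$magnitude[1], 1e-10)
})

test_that("mesh refinement changes |Z| at 10 kHz by less than 0.5%", {
  stack <- personalize_thicknesses(reference_profile("male"))
  z <- vapply(2:3, function(level)
    Mod(tetrapolar_impedance(knee_mesh(stack, "2d", resolution = level),
                             knee_mat, 1e4)), numeric(1))
  expect_lt(abs(z[2] - z[1]) / z[2], 0.005)
})

test_that("axial (parallel-fiber) conductivity matters less than transverse", {
  stack <- personalize_thicknesses(reference_profile("male"))
  mesh <- knee_mesh(stack, "3d", resolution = 1, axial_length_mm = 80)
  bump <- function(which_axis) {
    function(region, frequency) {
      s <- knee_mat(region, frequency)
      if (region == "muscle") s[[which_axis]] <- s[[which_axis]] * 3
      s
    }
  }
  z0 <- tetrapolar_impedance(mesh, knee_mat, 1e4)
  dz_par <- Mod(tetrapolar_impedance(mesh, bump("z"), 1e4) - z0)
  dz_perp <- Mod(tetrapolar_impedance(mesh, bump("t"), 1e4) - z0)
  expect_lt(dz_par, dz_perp)
})

test_that("an all-Neumann problem is rejected and currents need a terminal", {
  expect_error(boundary_spec(list()), class = "kneebis_validation_error")
  bnd <- boundary_spec(list(list(nodes = knee2d$patches[[1]], value = 1)))
  field <- solve_potential(knee2d, knee_mat, bnd, 1e4)
  expect_error(terminal_current(field, 2), class = "kneebis_validation_error")
})

test_that("the layered surrogate matches direct series arithmetic", {
  tab <- default_tissue_table()
  # five-layer reference stack at 1 kHz vs an independent hand sum
  st_a <- layer_stack(0.06, 4.501, 15.192, 19.607, 25.640)
  z_a <- analytic_layered_impedance(st_a, tab, area_mm2 = 400,
                                    frequencies = 1e3)
  z_hand <- 0 + 0i
  lay <- list(list("Dry Skin", 0.06), list("Wet Skin", 4.501),
              list("Fat", 15.192), list("Muscle (Parallel)", 19.607),
              list("Bone", 25.640))
  for (l in lay) {
    a <- cc_as_args(tab[[l[[1]]]])
    sig <- 1i * 2 * pi * 1e3 * EPS0_ORACLE *
      do.call(oracle_eps, c(a, list(f = 1e3)))
    z_hand <- z_hand + l[[2]] * 1e-3 / (sig * 400e-6)
  }
  expect_equal(z_a$z, z_hand, tolerance = 1e-12)

  # series additivity: doubling a layer thickness doubles its contribution
  s1 <- analytic_layered_impedance(layer_stack(2, 1e-9, 1e-9, 1e-9, 1e-9),
                                   tab, frequencies = 1e3)$z
  s2 <- analytic_layered_impedance(layer_stack(4, 1e-9, 1e-9, 1e-9, 1e-9),
                                   tab, frequencies = 1e3)$z
  expect_equal(s2, 2 * s1, tolerance = 1e-6)
})

test_that("layered FEM cross-check: radial current through a coated disc", {
  # 2D annulus with bipolar full-ring terminals is the radial analogue of the
  # series stack: log-shell resistances add. Use two shells of contrasting
  # conductivity and compare with the analytic series sum.
  stack <- layer_stack(5, 5, 5, 5, 30)   # interfaces at 30..50 mm
  mesh <- knee_mesh(stack, "2d", resolution = 2, electrodes = NULL)
  # inner disc r<30mm nearly perfect conductor; shells resistive
  mats <- function(region, frequency)
    switch(region, bone = c(t = 1e4 + 0i, z = 1e4 + 0i),
           muscle = c(t = 0.2 + 0i, z = 0.2 + 0i),
           fat = c(t = 0.05 + 0i, z = 0.05 + 0i),
           c(t = 0.5 + 0i, z = 0.5 + 0i))
  inner <- which(sqrt(rowSums(mesh$p^2)) < 30.0001e-3)
  bnd <- boundary_spec(list(list(nodes = inner, value = 1),
                            list(nodes = mesh$outer_nodes, value = 0)))
  field <- solve_potential(mesh, mats, bnd, 1e3)
  z <- 1 / terminal_current(field, 1)
  z_ref <- log(35 / 30) / (2 * pi * 0.2) + log(40 / 35) / (2 * pi * 0.05) +
    (log(45 / 40) + log(50 / 45)) / (2 * pi * 0.5) + 0  # per unit length
  expect_lt(Mod(z - z_ref) / Mod(z_ref), 0.01)
})
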