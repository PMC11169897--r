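test_that("reference table serves the tabulated feature values", {
  expect_equal(reference_spectra(array_spec(gap_nm = 1.5))$features$absorptance_peak,
               0.65)
  expect_equal(reference_spectra(array_spec(gap_nm = 5))$features$absorptance_peak,
               0.50)
  expect_equal(reference_spectra(array_spec(gap_nm = 1.5))$features$c_abs_at_anchor_nm2,
               1500)
  # printed orderings carried by the anchors
  ref <- vapply(c(1, 1.5, 2.5, 5), function(g)
    reference_spectra(array_spec(gap_nm = g))$features$absorptance_peak,
    numeric(1))
  expect_true(all(diff(ref) < 0))
  expect_error(reference_spectra(array_spec(gap_nm = 3)), "coupled_dipole")
  expect_error(reference_spectra(array_spec(radius_nm = 20)), "coupled_dipole")
})

test_that("ab_at answers at anchors, refuses off-anchor, computes otherwise", {
  arr15 <- array_spec(gap_nm = 1.5)
  expect_equal(ab_at(arr15, 453, "reference_table"), 0.65)
  expect_error(ab_at(arr15, 500, "reference_table"), "spot values")
  expect_error(ab_at(array_spec(gap_nm = 5), 453, "reference_table"),
               "spot values")
  a_cd <- ab_at(arr15, 453, "coupled_dipole")
  expect_true(a_cd >= 0 && a_cd <= 1)
})

test_that("coupled-dipole spectra conserve energy and keep channels bounded", {
  lam <- seq(341, 701, by = 4)
  for (g in c(1.5, 5)) {
    s <- coupled_dipole_spectra(array_spec(gap_nm = g), lam)$spectra
    expect_lt(max(abs(s$absorptance + s$reflectance + s$transmittance - 1)),
              1e-6)
    for (ch in c("absorptance", "reflectance", "transmittance"))
      expect_true(all(s[[ch]] >= 0 & s[[ch]] <= 1))
    expect_true(all(s$per_particle_c_abs_nm2 >= 0))
  }
})

test_that("array resonance blue-shifts as the interparticle gap grows", {
  lam <- seq(341, 701, by = 2)
  peak <- vapply(c(1, 1.5, 2.5, 5), function(g) {
    s <- coupled_dipole_spectra(array_spec(gap_nm = g), lam)$spectra
    s$wavelength_nm[which.max(s$absorptance)]
  }, numeric(1))
  expect_true(all(diff(peak) < 0))
  # and every array resonance sits red of the isolated-particle resonance
  iso <- find_lspr(particle_spec(25, medium = "water"))
  expect_true(all(peak > iso))
})

test_that("a sparse monolayer becomes transparent", {
  # pitch 350 nm stays subwavelength above 480 nm; off resonance the layer
  # barely interacts with the field
  s <- coupled_dipole_spectra(array_spec(gap_nm = 300),
                              seq(480, 700, by = 20))$spectra
  expect_true(all(s$transmittance > 0.9))
  expect_true(all(s$absorptance < 0.05))
})

test_that("dilute-limit per-particle absorption approaches the corrected single particle", {
  lam <- seq(360, 700, by = 10)
  p <- particle_spec(25, medium = "water")
  alpha <- polarizability(p, lam)
  k <- 2 * pi * nk_at(load_optical_constants("water"), lam)$n / lam
  alpha_r <- 1 / (1 / alpha - 1i * k^3 / (6 * pi))
  cs_single <- k * Im(alpha_r) - k^4 / (6 * pi) * Mod(alpha_r)^2
  pk <- lam[which.max(cs_single)]

  # pitch 10R: the lattice coupling is negligible and the array matches the
  # corrected single particle away from the resonance; at the resonance the
  # collective (specular) radiative damping k/2A_c differs irreducibly from
  # the isolated-dipole damping k^3/6pi (see the methods vignette)
  spd <- coupled_dipole_spectra(array_spec(gap_nm = 200), lam)$spectra
  ratio <- spd$per_particle_c_abs_nm2 / cs_single
  off <- lam - pk > 110
  expect_true(all(abs(ratio[off] - 1) < 0.05))

  # at the radiation-matched pitch (k/2A_c = k^3/6pi near the resonance,
  # pitch ~ 150 nm) the two damping channels coincide and the per-particle
  # absorption matches the single particle across the whole band
  spm <- coupled_dipole_spectra(array_spec(gap_nm = 100), lam)$spectra
  expect_true(all(abs(spm$per_particle_c_abs_nm2 / cs_single - 1) < 0.055))
})

test_that("geometry and numerical guards hold", {
  expect_error(array_spec(gap_nm = 0.5), ">= 1 nm")
  expect_error(array_spec(lattice = "square"), "staggered")
  expect_equal(array_spec(gap_nm = 1.5)$pitch_nm, 51.5)
  expect_error(coupled_dipole_spectra(array_spec(gap_nm = 500), 400),
               "subwavelength")
  expect_error(coupled_dipole_spectra(array_spec(gap_nm = 1.5), numeric(0)),
               "empty")
  expect_error(
    coupled_dipole_spectra(array_spec(gap_nm = 1.5), 453,
                           truncation_pitches = 2, convergence_tol = 1e-3),
    "not converged")
})
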