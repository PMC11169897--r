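# Independent oracle: the dipole-limit cross-sections assembled directly
# from the permittivities, kept free of the package's particle/spectrum
# machinery.
oracle_xsec <- function(r_nm, lam_nm, metal, medium) {
  eps_m <- permittivity(metal, lam_nm)
  eps_s <- permittivity(medium, lam_nm)
  V <- 4 / 3 * pi * r_nm^3
  alpha <- 3 * V * (eps_m - eps_s) / (eps_m + 2 * eps_s)
  kfac <- 2 * pi / lam_nm
  list(c_abs = kfac * Im(alpha),
       c_scat = kfac^4 / (6 * pi) * Mod(alpha)^2)
}

test_that("cross sections agree with the directly composed dipole formulas", {
  ag <- load_optical_constants("silver")
  blend <- load_optical_constants("active_blend")
  set.seed(42)
  r <- runif(20, 2, 40)
  lam <- runif(20, 260, 790)
  for (i in 1:20) {
    s <- cross_sections(particle_spec(r[i], ag, blend), lam[i])
    o <- oracle_xsec(r[i], lam[i], ag, blend)
    expect_equal(s$c_abs_nm2, o$c_abs, tolerance = 1e-12)
    expect_equal(s$c_scat_nm2, o$c_scat, tolerance = 1e-12)
    expect_equal(s$q_abs, o$c_abs / (pi * r[i]^2), tolerance = 1e-12)
    expect_equal(s$q_sc, o$c_scat / (o$c_scat + o$c_abs), tolerance = 1e-12)
  }
})

test_that("polarizability vanishes when index-matched and scales with volume", {
  m <- flat_material("m", 1.7, 0.0)
  expect_equal(polarizability(particle_spec(10, m, m), 500), 0 + 0i)

  ag <- load_optical_constants("silver")
  blend <- load_optical_constants("active_blend")
  a1 <- polarizability(particle_spec(10, ag, blend), 500)
  a2 <- polarizability(particle_spec(20, ag, blend), 500)
  expect_equal(a2, 8 * a1, tolerance = 1e-12)
})

test_that("lossless particle in lossless host absorbs nothing", {
  met <- flat_material("lossless_metal", 0.4, 0.0)
  host <- flat_material("host", 1.5, 0.0)
  s <- cross_sections(particle_spec(10, met, host), c(400, 500, 600))
  expect_equal(s$c_abs_nm2, rep(0, 3))
  expect_true(all(s$c_scat_nm2 > 0))
  expect_equal(s$q_sc, rep(1, 3))
})

test_that("peak efficiencies match the studied silver-in-blend magnitudes", {
  blend <- load_optical_constants("active_blend")
  ag <- load_optical_constants("silver")
  q_abs_ref <- c(1.2, 1.8, 2.4)
  q_scat_ref <- c(0.0015, 0.006, 0.019)
  radii <- c(5, 7.5, 10)
  peaks_abs <- peaks_scat <- numeric(3)
  for (i in 1:3) {
    s <- cross_sections(particle_spec(radii[i], ag, blend), 300:800)
    peaks_abs[i] <- max(s$q_abs)
    peaks_scat[i] <- max(s$q_scat)
    expect_lt(abs(peaks_abs[i] - q_abs_ref[i]) / q_abs_ref[i], 0.15)
    expect_lt(abs(peaks_scat[i] - q_scat_ref[i]) / q_scat_ref[i], 0.25)
  }
  # strictly increasing in radius, as is Q_sc at the resonance
  expect_true(all(diff(peaks_abs) > 0))
  expect_true(all(diff(peaks_scat) > 0))
  qsc <- vapply(radii, function(r) {
    p <- particle_spec(r, ag, blend)
    scattering_efficiency(cross_sections(p, 300:800), find_lspr(p))
  }, numeric(1))
  expect_true(all(diff(qsc) > 0))
})

test_that("scattering-to-absorption ratio scales as the particle volume", {
  ag <- load_optical_constants("silver")
  blend <- load_optical_constants("active_blend")
  ratio_at <- function(r, lam) {
    s <- cross_sections(particle_spec(r, ag, blend), lam)
    s$q_scat / s$q_abs
  }
  for (lam in c(380, 500, 600)) { # off the resonance wing
    expect_equal(ratio_at(20, lam) / ratio_at(10, lam), 8, tolerance = 0.2)
  }
})

test_that("resonance location behaves as the Froehlich condition predicts", {
  ag <- load_optical_constants("silver")
  blend <- load_optical_constants("active_blend")
  water <- load_optical_constants("water")
  p_blend <- particle_spec(10, ag, blend)
  lspr_blend <- find_lspr(p_blend)
  expect_true(abs(lspr_blend - 453) <= 2)

  # oracle: brute-force scan of the directly composed c_abs
  o <- oracle_xsec(10, 300:800, ag, blend)
  expect_identical(lspr_blend, (300:800)[which.max(o$c_abs)])

  # lower-index host shifts the crossing to shorter wavelengths
  expect_lt(find_lspr(particle_spec(10, ag, water)), lspr_blend)

  # a grid that does not bracket the resonance refuses
  expect_error(find_lspr(p_blend, 520:800), "boundary")
  expect_error(find_lspr(p_blend, 300:360), "boundary")
})

test_that("scattering efficiency is the defined ratio and guards its domain", {
  ag <- load_optical_constants("silver")
  blend <- load_optical_constants("active_blend")
  s <- cross_sections(particle_spec(7.5, ag, blend), 300:800)
  expect_equal(s$q_sc, s$c_scat_nm2 / (s$c_scat_nm2 + s$c_abs_nm2),
               tolerance = 1e-12)
  expect_true(all(s$q_sc >= 0 & s$q_sc <= 1))
  # interpolated query sits between neighbouring grid ratios
  v <- scattering_efficiency(s, 453.5)
  expect_true(v >= min(s$q_sc[s$wavelength_nm %in% 453:454]) &&
                v <= max(s$q_sc[s$wavelength_nm %in% 453:454]))
  expect_error(scattering_efficiency(s, 900), "grid")
  # index-matched particle: zero cross-sections, efficiency undefined
  m <- flat_material("m", 1.7)
  s0 <- cross_sections(particle_spec(10, m, m), c(400, 500))
  expect_error(scattering_efficiency(s0, 450), "undefined")
})

test_that("domain guards: radius, grids and conventions", {
  expect_error(particle_spec(60), "50 nm")
  ag <- load_optical_constants("silver")
  blend <- load_optical_constants("active_blend")
  expect_error(cross_sections(particle_spec(10, ag, blend), numeric(0)),
               "empty")
  # the in-medium wavelength convention stays available as a flag and
  # rescales the absorption prefactor by the host index
  s_v <- cross_sections(particle_spec(10, ag, blend), 500)
  s_m <- cross_sections(particle_spec(10, ag, blend), 500,
                        medium_wavelength = TRUE)
  n_s <- nk_at(blend, 500)$n
  expect_equal(s_m$c_abs_nm2, n_s * s_v$c_abs_nm2, tolerance = 1e-12)
  expect_equal(s_m$c_scat_nm2, n_s^4 * s_v$c_scat_nm2, tolerance = 1e-12)
})
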