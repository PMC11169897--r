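test_that("generation rate is the closed-form photon balance", {
  expect_equal(generation_rate(1e6, 453, 0, 0.7), 0)
  g1 <- generation_rate(1.7e6, 453, 260, 0.7)
  expect_equal(generation_rate(1.7e6, 453, 520, 0.7), 2 * g1)
  # direct arithmetic oracle: alpha * lambda * I0 * P / (h c)
  expect_equal(g1, 1.7e6 * 453e-9 * 260 * 0.7 /
                 (6.62607015e-34 * 2.99792458e8), tolerance = 1e-12)
  # the calibration anchor scale: G q L of that order is a few A/m^2
  expect_equal(g1 * 1.602176634e-19 * 70e-9, 7.91, tolerance = 0.01)
})

test_that("bare-layer short-circuit current reproduces the study anchors", {
  expect_equal(jsc_bare(scenario_bare(453, 0.26)), 7.5, tolerance = 1e-9)
  expect_equal(jsc_bare(scenario_bare(250, 0.26)), 19, tolerance = 1e-9)
  # the text-quoted rounded magnitude at the resonance wavelength
  expect_true(jsc_bare(scenario_bare(453, 0.26)) > 7 &&
                jsc_bare(scenario_bare(453, 0.26)) < 9)
  # linear in intensity
  expect_equal(jsc_bare(scenario_bare(453, 0.52)), 15, tolerance = 1e-9)
})

test_that("near-field volume ratio follows the Q_abs^(3/2) convention", {
  expect_equal(volume_ratio_v1(1), 1)
  expect_equal(volume_ratio_v1(2.4), 2.4^1.5)
  # the printed radius scaling of the J_sc slopes, 1 : 1.8 : 2.8
  v1 <- volume_ratio_v1(c(1.2, 1.8, 2.4))
  expect_equal(v1 / v1[1], c(1, 1.8, 2.8), tolerance = 0.03)
})

test_that("cathode volume ratio matches a brute-force lattice count", {
  sc <- device_scenario()
  expect_equal(volume_ratio_v2(0, sc), 0)
  v2 <- volume_ratio_v2(1500, sc)
  expect_equal(volume_ratio_v2(750, sc), v2 / 2, tolerance = 1e-12)
  # oracle: enumerate hexagonal sites over the 100x100 um cell
  pitch <- 2 * sc$k_radius_nm + sc$k_gap_nm
  side <- sc$cell_side_um * 1e3
  nmax <- ceiling(side / pitch) + 2
  ij <- expand.grid(i = -nmax:(2 * nmax), j = -nmax:(2 * nmax))
  x <- pitch * (ij$i + ij$j / 2)
  y <- pitch * ij$j * sqrt(3) / 2
  n_cell <- sum(x >= 0 & x < side & y >= 0 & y < side)
  v2_count <- n_cell * 1500 * 25 / (side^2 * sc$layer_L_nm)
  expect_equal(v2, v2_count, tolerance = 0.005)
})

test_that("composite model degenerates, decomposes and scales correctly", {
  sc0 <- scenario_bare()
  expect_equal(jsc_composite(sc0)$jsc_total, jsc_bare(sc0), tolerance = 1e-12)

  b <- jsc_composite(scenario_preferred())
  expect_equal(b$jsc_total, b$term_bare + b$term_a_np + b$term_k_np,
               tolerance = 1e-12)
  expect_true(all(c(b$term_bare, b$term_a_np, b$term_k_np) >= 0))
  expect_true(b$k_coeff >= 0 && b$k_coeff <= 1)

  # linear in incident intensity up to the (weakly) intensity-independent
  # transmittance factors
  b2 <- jsc_composite(scenario_preferred(intensity_mW_mm2 = 0.52))
  expect_equal(b2$jsc_total, 2 * b$jsc_total, tolerance = 1e-9)
})

test_that("composite current grows with radius and filling fraction", {
  grid <- expand.grid(r = c(5, 7.5, 10), f = c(0.05, 0.075, 0.10))
  J <- matrix(vapply(seq_len(nrow(grid)), function(i)
    jsc_composite(device_scenario(a_radius_nm = grid$r[i],
                                  fill_fraction = grid$f[i]))$jsc_total,
    numeric(1)), nrow = 3)
  expect_true(all(apply(J, 1, diff) > 0)) # increasing in f at each radius
  expect_true(all(apply(J, 2, diff) > 0)) # increasing in r at each filling
})

test_that("the cathode term adds a nearly constant current across fillings", {
  inc <- vapply(c(0.05, 0.075, 0.10), function(f) {
    w <- jsc_composite(device_scenario(a_radius_nm = 7.5, fill_fraction = f,
                                       intensity_mW_mm2 = 0.33))$jsc_total
    wo <- jsc_composite(device_scenario(a_radius_nm = 7.5, fill_fraction = f,
                                        intensity_mW_mm2 = 0.33,
                                        include_k_term = FALSE))$jsc_total
    w - wo
  }, numeric(1))
  expect_lt(max(abs(inc / mean(inc) - 1)), 0.15)
})

test_that("one-point calibration predicts the remaining printed grid", {
  grid <- printed_jsc_grid()
  for (i in seq_len(nrow(grid))) {
    J <- jsc_composite(grid_scenario(grid[i, ]))$jsc_total
    expect_lt(abs(J - grid$jsc[i]), 2)
  }
})

test_that("an over-committed layer volume is refused, not clipped", {
  cal <- pv_calibration()
  cal$photocurrent$l_influence_nm <- 700 # absurd influence depth
  expect_error(jsc_composite(scenario_preferred(), cal), "negative")
})
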