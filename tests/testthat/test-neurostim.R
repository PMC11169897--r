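test_that("plate field is linear, edge-peaked and conductivity-scaled", {
  e <- electrode_spec()
  prof0 <- plate_current_profile(e, 0, line_standoff_um = 2)
  expect_true(all(prof0$j_A_m2 == 0))
  expect_true(all(prof0$phi_V == 0))

  prof <- plate_current_profile(e, -0.11, line_standoff_um = 2)
  centre <- mean(prof$j_A_m2[abs(prof$x_um) < 20])
  edge <- max(prof$j_A_m2[abs(abs(prof$x_um) - 50) < 5])
  far <- max(prof$j_A_m2[abs(prof$x_um) > 150])
  expect_gt(edge, 1.5 * centre)   # sharp peaks at the plate edges
  expect_lt(far, 0.3 * centre)    # field confined to the footprint
  # plateau: the central third varies much less than the edge contrast
  inner <- prof$j_A_m2[abs(prof$x_um) < 16]
  expect_lt(max(inner) / min(inner), 1.3)

  # linearity in the drive voltage
  prof2 <- plate_current_profile(e, -0.22, line_standoff_um = 2)
  expect_equal(prof2$j_z_A_m2, 2 * prof$j_z_A_m2, tolerance = 1e-12)
  expect_equal(mean(prof2$j_A_m2), 2 * mean(prof$j_A_m2), tolerance = 1e-12)

  # doubling the conductivity doubles the delivered current at fixed V
  e2 <- electrode_spec(conductivity_S_per_m = 2 * e$conductivity_S_per_m)
  prof_s <- plate_current_profile(e2, -0.11, line_standoff_um = 2)
  expect_equal(prof_s$j_A_m2, 2 * prof$j_A_m2, tolerance = 1e-9)

  expect_error(plate_current_profile(e, -0.1, n_patch = 10), "20 patches")
})

test_that("a field-free membrane stays at rest", {
  a <- axon_spec()
  tr <- simulate_membrane(a, rep(0, 100), stimulus_pulse(0, 1))
  expect_lt(max(abs(tr$vm_mV + 65)), 0.1)
})

test_that("suprathreshold cathodic pulses elicit a propagating action potential", {
  e <- electrode_spec(); a <- axon_spec()
  th <- threshold_search(e, a)
  expect_true(is.finite(th) && th > 0)

  x <- (seq_len(100) - 50.5) * a$compartment_um
  shape <- plate_potential_line(e, x)
  supra <- simulate_membrane(a, -1.2 * th * shape, stimulus_pulse(-1.2 * th, 1))
  expect_true(has_spike(supra))
  # full-height spike: excursion above 80 mV from rest
  expect_gt(max(supra$vm_mV) + 65, 80)
  # propagation reaches both fibre ends away from the electrode footprint
  left <- supra$vm_mV[, 5]; right <- supra$vm_mV[, 96]
  expect_gt(max(left), 0); expect_gt(max(right), 0)

  # all-or-none: just below threshold the fibre relaxes back to rest
  sub <- simulate_membrane(a, -0.97 * th * shape, stimulus_pulse(-0.97 * th, 1))
  expect_false(has_spike(sub))
  expect_lt(max(abs(sub$vm_mV[nrow(sub$vm_mV), ] + 65)), 5)
  # spike amplitude is insensitive to the drive 10% vs 30% above threshold
  supra2 <- simulate_membrane(a, -1.1 * th * shape, stimulus_pulse(-1.1 * th, 1))
  expect_lt(abs(max(supra2$vm_mV) - max(supra$vm_mV)) /
              (max(supra$vm_mV) + 65), 0.05)
})

test_that("threshold obeys strength-duration and distance ordering", {
  e <- electrode_spec(); a <- axon_spec()
  th_05 <- threshold_search(e, a, pulse_duration_ms = 0.5)
  th_1 <- threshold_search(e, a, pulse_duration_ms = 1)
  th_2 <- threshold_search(e, a, pulse_duration_ms = 2)
  expect_true(th_05 >= th_1 && th_1 >= th_2) # non-increasing in duration
  expect_gt(th_05, th_2)                     # and strictly so across 4x

  e10 <- electrode_spec(standoff_um = 10)
  expect_gt(threshold_search(e10, a), th_1)  # farther fibre is harder
})

test_that("threshold is stable under space-time refinement", {
  e <- electrode_spec()
  th <- threshold_search(e, axon_spec(compartment_um = 4), dt_ms = 0.025)
  th_fine <- threshold_search(e, axon_spec(compartment_um = 2),
                              dt_ms = 0.0125)
  expect_lt(abs(th_fine - th) / th, 0.05)
})

test_that("integration and sampling guards refuse invalid setups", {
  a <- axon_spec()
  expect_error(simulate_membrane(a, rep(0, 40), stimulus_pulse(0, 1)),
               "every compartment")
  expect_error(simulate_membrane(a, rep(0, 100), stimulus_pulse(0, 1),
                                 dt_ms = 0.5), "dt_ms")
  expect_error(axon_spec(compartment_um = 8), "<= 5")
  expect_error(axon_spec(membrane_model = "passive"), "Hodgkin")
})
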