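#' Run the full model chain for one device scenario
#'
#' Composes the whole pipeline: single-particle optics, cathode-array
#' absorptance, Beer-Lambert attenuation, composite photocurrent, the
#' calibrated diode curve, the electrode load-line operating point, the
#' water-window safety flags and the stimulation verdict (operating-point
#' current density against the activation threshold). Every calibrated
#' constant that entered is echoed under `$provenance`.
#'
#' @param scenario [device_scenario()], or the path of a YAML scenario file
#' @param cal calibration list
#' @param z_interface electrode areal impedance (Ohm m^2)
#' @param j_threshold activation threshold current density (A/m^2)
#' @return object of class `pipeline_report`
#' @export
run_scenario <- function(scenario, cal = pv_calibration(),
                         z_interface = cal$electrode$z_interface_ohm_m2,
                         j_threshold = cal$electrode$j_threshold_A_m2) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  stopifnot(inherits(scenario, "device_scenario"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  optics <- stage("quasistatic_optics", {
    if (scenario$fill_fraction > 0) {
      p <- particle_spec(scenario$a_radius_nm,
                         metal = cal_fixture(cal, "silver"),
                         medium = cal_fixture(cal, "active_blend"))
      s <- cross_sections(p, 300:800)
      i <- which.max(s$c_abs_nm2)
      list(lspr_nm = s$wavelength_nm[i], q_abs_peak = s$q_abs[i],
           q_scat_peak = max(s$q_scat),
           q_sc_at_peak = s$q_sc[i])
    } else NULL
  })
  atten <- stage("attenuation", total_transmittance(scenario, cal))
  jsc <- stage("photocurrent", jsc_composite(scenario, cal))
  ref <- stage("device_reference", device_reference_lookup(scenario))
  curve <- stage("device_circuit", {
    params <- calibrate_diode(ref$jsc_A_m2, ref$voc_V, ref$ff_pct / 100)
    iv_curve(params, jsc$jsc_total,
             p_in = intensity_W_m2(scenario$intensity_mW_mm2))
  })
  op <- stage("operating_point",
              operating_point(curve, z_interface, j_threshold))

  structure(list(
    scenario = scenario,
    optics = optics,
    a_b = jsc$a_b, t_r = atten$t_total,
    attenuation = atten,
    jsc = jsc,
    iv = list(jsc = attr(curve, "jsc"), voc = attr(curve, "voc"),
              ff = attr(curve, "ff"), pmax = attr(curve, "pmax"),
              pce = attr(curve, "pce")),
    curve = curve,
    operating_point = op,
    water_window = list(
      operating = water_window_check(op$voltage),
      open_circuit = water_window_check(attr(curve, "voc"))),
    stimulates = op$stimulates,
    provenance = list(
      kappa_A = cal$photocurrent$kappa_A,
      kappa_K = cal$photocurrent$kappa_K,
      kappa_np = cal$attenuation$kappa_np,
      layer_path_nm = cal$attenuation$layer_path_nm,
      l_influence_nm = cal$photocurrent$l_influence_nm,
      silver_gamma_eV = cal$silver$gamma_eV,
      blend_cauchy_A = cal$blend$cauchy_A,
      anchors = cal$anchors,
      z_interface_ohm_m2 = z_interface,
      j_threshold_A_m2 = j_threshold)
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== plasmopv pipeline report ==\n")
  print(x$scenario)
  if (!is.null(x$optics))
    cat(sprintf("  LSPR %g nm | peak Q_abs %.3f, Q_scat %.4f, Q_sc %.4f\n",
                x$optics$lspr_nm, x$optics$q_abs_peak, x$optics$q_scat_peak,
                x$optics$q_sc_at_peak))
  cat(sprintf("  T_r = %.4f, A_b = %s\n", x$t_r,
              if (is.na(x$a_b)) "-" else sprintf("%.2f", x$a_b)))
  cat(sprintf("  J_sc = %.2f A/m^2 (bulk %.2f + A-NP %.2f + K-NP %.2f)\n",
              x$jsc$jsc_total, x$jsc$term_bare, x$jsc$term_a_np,
              x$jsc$term_k_np))
  cat(sprintf("  V_oc = %.3f V, FF = %.1f%%, P_max = %.2f W/m^2, PCE = %.2f%%\n",
              x$iv$voc, 100 * x$iv$ff, x$iv$pmax, 100 * x$iv$pce))
  cat(sprintf("  operating point: %.4f V, %.2f A/m^2 -> stimulates: %s\n",
              x$operating_point$voltage, x$operating_point$current_density,
              x$stimulates))
  cat(sprintf("  water window: operating %s, open-circuit %s\n",
              x$water_window$operating, x$water_window$open_circuit))
  invisible(x)
}

#' Performance table over a list of scenarios
#'
#' One row per scenario with the modelled J_sc and the diode-curve
#' performance scalars, mirroring the reference performance table layout
#' (configuration, incident intensity, J_sc, V_oc, FF, PCE).
#'
#' @param scenarios list of [device_scenario()] objects
#' @param cal calibration list
#' @return data frame with one row per scenario
#' @export
compare_table <- function(scenarios, cal = pv_calibration()) {
  if (inherits(scenarios, "device_scenario")) scenarios <- list(scenarios)
  stopifnot(length(scenarios) >= 1)
  rows <- lapply(scenarios, function(sc) {
    rep <- run_scenario(sc, cal)
    data.frame(
      configuration = if (sc$fill_fraction == 0)
        sprintf("bare, %g nm", sc$wavelength_nm)
      else sprintf("r=%g nm, f_s=%g%%%s", sc$a_radius_nm,
                   100 * sc$fill_fraction,
                   if (sc$include_k_term) ", with K" else ", w/o K"),
      intensity_mW_mm2 = sc$intensity_mW_mm2,
      jsc_A_m2 = rep$jsc$jsc_total,
      voc_V = rep$iv$voc,
      ff_pct = 100 * rep$iv$ff,
      pce_pct = 100 * rep$iv$pce)
  })
  do.call(rbind, rows)
}
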