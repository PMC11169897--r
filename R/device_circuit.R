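#' Single-diode equivalent-circuit parameters
#'
#' Lumped substitute for a full drift-diffusion device solve:
#' J(V) = J_sc - J0 (exp(V / (n Vt)) - 1) - V / R_shunt, with an optional
#' series resistance handled implicitly. Parameters are fitted per device
#' configuration to its (J_sc, V_oc, FF) triple.
#'
#' @param j0 reverse saturation current density (A/m^2), > 0
#' @param ideality diode ideality factor n, > 0
#' @param r_series areal series resistance (Ohm m^2), >= 0
#' @param r_shunt areal shunt resistance (Ohm m^2), > 0 (may be Inf)
#' @param temperature cell temperature (K)
#' @return object of class `diode_params`
#' @export
diode_params <- function(j0, ideality, r_series = 0, r_shunt = Inf,
                         temperature = 300) {
  stopifnot(j0 > 0, ideality > 0, r_series >= 0, r_shunt > 0,
            temperature > 0)
  structure(list(j0 = j0, ideality = ideality, r_series = r_series,
                 r_shunt = r_shunt, temperature = temperature,
                 vt = pv_constants$kB * temperature / pv_constants$q),
            class = "diode_params")
}

# Device current density (A/m^2) at terminal voltage v (V), photovoltaic
# quadrant magnitudes. Vectorized over v.
diode_current <- function(params, v, jsc) {
  nvt <- params$ideality * params$vt
  if (params$r_series == 0) {
    j <- jsc - params$j0 * (exp(v / nvt) - 1)
    if (is.finite(params$r_shunt)) j <- j - v / params$r_shunt
    return(j)
  }
  vapply(v, function(vv) {
    f <- function(j) {
      vd <- vv + j * params$r_series
      jsc - params$j0 * (exp(vd / nvt) - 1) -
        (if (is.finite(params$r_shunt)) vd / params$r_shunt else 0) - j
    }
    stats::uniroot(f, c(-10 * abs(jsc) - 1, 10 * abs(jsc) + 1),
                   tol = 1e-12)$root
  }, numeric(1))
}

diode_voc <- function(params, jsc) {
  if (jsc <= 0) return(0)
  stats::uniroot(function(v) diode_current(params, v, jsc),
                 c(0, 5), tol = 1e-12)$root
}

#' Fit the single-diode model to a (J_sc, V_oc, FF) triple
#'
#' The saturation current is set analytically from V_oc; the ideality
#' factor is then the unique root matching the fill factor (FF is strictly
#' decreasing in the ideality at fixed V_oc). Series and shunt resistance
#' stay at their ideal values (0, Inf): the studied fill factors all lie
#' inside the range the ideality alone spans. Deterministic: bracketed
#' bisection with fixed bounds.
#'
#' @param jsc short-circuit current density (A/m^2), > 0
#' @param voc open-circuit voltage (V), > 0
#' @param ff fill factor as a fraction in (0, 1)
#' @return [diode_params()] whose curve reproduces `voc` (machine
#'   precision) and `ff` (root tolerance)
#' @export
calibrate_diode <- function(jsc, voc, ff) {
  stopifnot(jsc > 0, voc > 0, ff > 0, ff < 1)
  vt <- pv_constants$kB * 300 / pv_constants$q
  ff_of_n <- function(n) {
    j0 <- jsc / (exp(voc / (n * vt)) - 1)
    p <- diode_params(j0, n)
    opt <- stats::optimize(function(v) -v * diode_current(p, v, jsc),
                           c(0, voc), tol = 1e-10)
    -opt$objective / (jsc * voc)
  }
  lo <- 0.3; hi <- 8
  f_lo <- ff_of_n(lo); f_hi <- ff_of_n(hi)
  if (ff > f_lo || ff < f_hi)
    stop(sprintf(
      "fill factor %.3f not achievable at V_oc = %.3f V; closest achievable: %.3f",
      ff, voc, if (ff > f_lo) f_lo else f_hi))
  n <- stats::uniroot(function(n) ff_of_n(n) - ff, c(lo, hi),
                      tol = 1e-10)$root
  diode_params(jsc / (exp(voc / (n * vt)) - 1), n)
}

#' Current-voltage and power-voltage curve of the device
#'
#' Evaluates the diode model on a 1-mV grid from 0 to 1.1 x V_oc and
#' extracts the performance scalars: J_sc, V_oc, maximum power density
#' P_max, fill factor FF = P_max / (J_sc V_oc) and power-conversion
#' efficiency PCE = P_max / P_in.
#'
#' @param params [diode_params()]
#' @param jsc short-circuit current density (A/m^2), >= 0
#' @param p_in incident power density (W/m^2), > 0
#' @return object of class `iv_curve`: data frame (`voltage_V`,
#'   `current_density_A_m2`, `power_W_m2`) with scalar attributes
#' @export
iv_curve <- function(params, jsc, p_in) {
  stopifnot(inherits(params, "diode_params"), p_in > 0, jsc >= 0)
  voc <- diode_voc(params, jsc)
  v <- if (voc > 0) seq(0, 1.1 * voc, by = 1e-3) else 0
  j <- diode_current(params, v, jsc)
  pw <- v * j
  out <- data.frame(voltage_V = v, current_density_A_m2 = j,
                    power_W_m2 = pw)
  pmax <- max(pw)
  attr(out, "params") <- params
  attr(out, "jsc") <- jsc
  attr(out, "voc") <- voc
  attr(out, "pmax") <- pmax
  attr(out, "ff") <- if (jsc > 0 && voc > 0) pmax / (jsc * voc) else NA_real_
  attr(out, "pce") <- pmax / p_in
  attr(out, "p_in") <- p_in
  class(out) <- c("iv_curve", "data.frame")
  out
}

#' @export
print.iv_curve <- function(x, ...) {
  cat(sprintf(
    "<iv_curve> Jsc=%.2f A/m^2, Voc=%.4f V, FF=%.1f%%, Pmax=%.2f W/m^2, PCE=%.2f%%\n",
    attr(x, "jsc"), attr(x, "voc"), 100 * attr(x, "ff"),
    attr(x, "pmax"), 100 * attr(x, "pce")))
  invisible(x)
}

#' Electrode-electrolyte interface load line
#'
#' Linear relation J(V) = V / Z through the origin (magnitudes; the
#' cathodic sign is applied only at the neural-stimulation boundary).
#'
#' @param z_interface areal interface impedance (Ohm m^2), > 0
#' @return function mapping voltage (V) to current density (A/m^2)
#' @export
load_line <- function(z_interface) {
  stopifnot(z_interface > 0)
  function(v) v / z_interface
}

#' Operating point of device curve and electrode load line
#'
#' Bisection intersection of the diode curve with J = V / Z on [0, V_oc];
#' the `stimulates` flag marks whether the delivered current density
#' reaches the activation threshold.
#'
#' @param curve [iv_curve()]
#' @param z_interface areal interface impedance (Ohm m^2), > 0
#' @param j_threshold activation threshold current density (A/m^2)
#' @return object of class `operating_point`: list(voltage, current_density,
#'   stimulates)
#' @export
operating_point <- function(curve, z_interface,
                            j_threshold = pv_calibration()$electrode$j_threshold_A_m2) {
  stopifnot(inherits(curve, "iv_curve"), z_interface > 0)
  params <- attr(curve, "params"); jsc <- attr(curve, "jsc")
  voc <- attr(curve, "voc")
  f <- function(v) diode_current(params, v, jsc) - v / z_interface
  if (jsc <= 0 || voc <= 0) {
    v_op <- 0; j_op <- 0
  } else {
    if (f(0) < 0 || f(voc) > 0)
      stop("no operating point in [0, V_oc]")
    v_op <- stats::uniroot(f, c(0, voc), tol = 1e-12)$root
    j_op <- v_op / z_interface
  }
  structure(list(voltage = v_op, current_density = j_op,
                 stimulates = j_op >= j_threshold,
                 j_threshold = j_threshold,
                 z_interface = z_interface),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf(
    "<operating_point> V=%.4f V, J=%.2f A/m^2, stimulates=%s (threshold %.1f A/m^2)\n",
    x$voltage, x$current_density, x$stimulates, x$j_threshold))
  invisible(x)
}

#' Water-window safety check
#'
#' TRUE iff |voltage| < 1.23 V, the electrolysis window of water; electrode
#' potentials inside the window cannot drive water oxidation/reduction.
#'
#' @param voltage electrode voltage (V), any sign
#' @return logical
#' @export
water_window_check <- function(voltage) {
  abs(voltage) < 1.23
}

#' Areal interface impedance from a threshold voltage/current pair
#'
#' Z = |V| / J.
#'
#' @param v_threshold threshold voltage (V)
#' @param j_threshold threshold current density (A/m^2), > 0
#' @return impedance (Ohm m^2); multiply by 1000 for kOhm mm^2
#' @export
interface_impedance <- function(v_threshold, j_threshold) {
  stopifnot(all(j_threshold > 0))
  abs(v_threshold) / j_threshold
}

#' Minimum light intensity that reaches the activation threshold
#'
#' J_sc is linear in the incident intensity, so the device curve is rescaled
#' from the scenario's modelled J_sc while the diode shape stays fixed at
#' the configuration's calibrated parameters; a bisection over intensity
#' finds the smallest value whose operating point delivers at least
#' `j_threshold`.
#'
#' @param scenario [device_scenario()]
#' @param z_interface areal interface impedance (Ohm m^2)
#' @param j_threshold activation threshold (A/m^2)
#' @param cal calibration list
#' @param resolution intensity resolution (mW/mm^2)
#' @param cap upper search bound (mW/mm^2)
#' @return threshold intensity (mW/mm^2), reported at the first stimulating
#'   bisection bracket
#' @export
threshold_intensity <- function(scenario,
                                z_interface = pv_calibration()$electrode$z_interface_ohm_m2,
                                j_threshold = pv_calibration()$electrode$j_threshold_A_m2,
                                cal = pv_calibration(),
                                resolution = 0.005, cap = 5) {
  stopifnot(inherits(scenario, "device_scenario"))
  ref <- device_reference_lookup(scenario)
  params <- calibrate_diode(ref$jsc_A_m2, ref$voc_V, ref$ff_pct / 100)
  jsc_ref <- jsc_composite(scenario, cal)$jsc_total
  i_ref <- scenario$intensity_mW_mm2
  j_op <- function(intensity) {
    crv <- iv_curve(params, jsc_ref * intensity / i_ref,
                    p_in = intensity_W_m2(intensity))
    operating_point(crv, z_interface, j_threshold)$current_density
  }
  if (j_threshold <= 0) return(resolution)
  lo <- 0; hi <- cap
  if (j_op(hi) < j_threshold)
    stop(sprintf("threshold not reachable below the %.2f mW/mm^2 cap", cap))
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (j_op(mid) >= j_threshold) hi <- mid else lo <- mid
  }
  hi
}

#' Packaged reference device performance table
#'
#' Published performance triples (J_sc, V_oc, FF, PCE) of the modelled
#' configurations; the single-diode substitute for the full device solve is
#' calibrated against these rows.
#'
#' @return data frame with one row per configuration
#' @export
device_reference <- function() {
  if (is.null(.pv_env$device_reference)) {
    path <- system.file("extdata", "device_reference.tsv",
                        package = "plasmopv", mustWork = TRUE)
    .pv_env$device_reference <- utils::read.table(path, header = TRUE,
                                                  sep = "\t")
  }
  .pv_env$device_reference
}

# Match a scenario to its reference row (bare rows by wavelength/intensity,
# embedded rows by radius/filling/intensity).
device_reference_lookup <- function(scenario) {
  tab <- device_reference()
  if (scenario$fill_fraction == 0) {
    hit <- tab$fill_fraction == 0 &
      tab$wavelength_nm == scenario$wavelength_nm &
      tab$intensity_mW_mm2 == scenario$intensity_mW_mm2
  } else {
    hit <- tab$fill_fraction == scenario$fill_fraction &
      !is.na(tab$radius_nm) & tab$radius_nm == scenario$a_radius_nm &
      tab$intensity_mW_mm2 == scenario$intensity_mW_mm2
  }
  if (sum(hit) != 1L)
    stop("no unique reference device row for this scenario configuration")
  tab[hit, , drop = FALSE]
}
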