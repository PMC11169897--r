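#' Stimulating plate-electrode specification
#'
#' Square equipotential plate (the cathode pixel) in a conductive tissue
#' half-space. The capacitive tissue response at the 10-Hz computational
#' frequency is folded into the resistive solution; the relative
#' permittivity is carried for reference only.
#'
#' @param side_um plate side length (um)
#' @param thickness_nm plate thickness (nm); the K-AgNP diameter
#' @param standoff_um distance from plate surface to the axon line (um)
#' @param conductivity_S_per_m tissue conductivity (S/m)
#' @param rel_permittivity tissue relative permittivity at 10 Hz
#' @return object of class `electrode_spec`
#' @export
electrode_spec <- function(side_um = 100, thickness_nm = 50,
                           standoff_um = 5, conductivity_S_per_m = 0.027,
                           rel_permittivity = 4.06e7) {
  stopifnot(side_um > 0, thickness_nm > 0, standoff_um > 0,
            conductivity_S_per_m > 0, rel_permittivity > 0)
  structure(list(side_um = side_um, thickness_nm = thickness_nm,
                 standoff_um = standoff_um,
                 conductivity_S_per_m = conductivity_S_per_m,
                 rel_permittivity = rel_permittivity),
            class = "electrode_spec")
}

#' Unmyelinated axon cable specification
#'
#' @param diameter_um fibre diameter (um); 1 um is within the human retinal
#'   ganglion-cell axon range
#' @param length_um modelled fibre length (um); should span at least 4x the
#'   electrode side so the boundary conditions do not touch the excited
#'   region
#' @param compartment_um compartment length (um); <= 5 um for convergence
#' @param membrane_model membrane label; only "hh" (classical
#'   Hodgkin-Huxley, 6.3 C squid kinetics) is implemented
#' @param axial_resistivity_ohm_cm axoplasmic resistivity (Ohm cm)
#' @return object of class `axon_spec`
#' @export
axon_spec <- function(diameter_um = 1, length_um = 400, compartment_um = 4,
                      membrane_model = "hh",
                      axial_resistivity_ohm_cm = 100) {
  stopifnot(diameter_um > 0, length_um > 0, compartment_um > 0,
            axial_resistivity_ohm_cm > 0)
  if (compartment_um > 5)
    stop("compartment_um must be <= 5 um (spatial convergence)")
  if (!identical(membrane_model, "hh"))
    stop("only the classical Hodgkin-Huxley membrane is implemented")
  structure(list(diameter_um = diameter_um, length_um = length_um,
                 compartment_um = compartment_um,
                 membrane_model = membrane_model,
                 axial_resistivity_ohm_cm = axial_resistivity_ohm_cm),
            class = "axon_spec")
}

#' Rectangular cathodic stimulus pulse
#'
#' @param amplitude_V electrode voltage during the pulse (V); cathodic
#'   stimulation uses negative values
#' @param duration_ms pulse duration (ms), > 0
#' @param period_ms repetition period (ms); informational, a single pulse
#'   is simulated
#' @return object of class `stimulus_pulse`
#' @export
stimulus_pulse <- function(amplitude_V = -0.11, duration_ms = 1,
                           period_ms = 100) {
  stopifnot(duration_ms > 0, period_ms > 0)
  structure(list(amplitude_V = amplitude_V, duration_ms = duration_ms,
                 period_ms = period_ms),
            class = "stimulus_pulse")
}

# Method-of-moments solve of the equipotential square plate at 1 V in a
# conductive half-space: patch currents I_j (A) such that the potential at
# every patch centre equals 1 V. Kernel 1/(2 pi sigma R); the self term is
# integrated by 16x16 subdivision.
plate_mom_solve <- function(e, n_patch = 24) {
  if (n_patch < 20)
    stop("at least 20 patches per side are needed to resolve the edge current peaks")
  side <- e$side_um * 1e-6
  a <- side / n_patch
  xc <- (seq_len(n_patch) - (n_patch + 1) / 2) * a
  centers <- as.matrix(expand.grid(x = xc, y = xc))
  np <- nrow(centers)
  dx <- outer(centers[, 1], centers[, 1], "-")
  dy <- outer(centers[, 2], centers[, 2], "-")
  R <- sqrt(dx^2 + dy^2)
  # self term: mean inverse distance from patch centre over the patch
  m <- 16
  sub <- (seq_len(m) - (m + 1) / 2) * (a / m)
  sg <- expand.grid(x = sub, y = sub)
  self_inv <- mean(1 / sqrt(sg$x^2 + sg$y^2)) # subcell centres avoid r = 0
  inv <- 1 / R
  diag(inv) <- self_inv
  G <- inv / (2 * pi * e$conductivity_S_per_m)
  I <- solve(G, rep(1, np))
  list(centers = centers, currents = I, patch_side = a, n_patch = n_patch)
}

plate_solution <- function(e, n_patch = 24) {
  key <- sprintf("plate_%g_%g_%d", e$side_um, e$conductivity_S_per_m, n_patch)
  if (is.null(.pv_env[[key]])) .pv_env[[key]] <- plate_mom_solve(e, n_patch)
  .pv_env[[key]]
}

# Potential (V per volt of electrode drive) at points (x, y, z) in metres.
plate_potential_at <- function(sol, e, x, y, z) {
  phi <- numeric(length(x))
  sigma <- e$conductivity_S_per_m
  for (j in seq_along(sol$currents)) {
    R <- sqrt((x - sol$centers[j, 1])^2 + (y - sol$centers[j, 2])^2 + z^2)
    phi <- phi + sol$currents[j] / (2 * pi * sigma * R)
  }
  phi
}

#' Current-density profile along a line above the plate electrode
#'
#' Method-of-moments solution of the equipotential plate in the tissue
#' half-space, sampled along a line parallel to the plate through its
#' centre at the given standoff. The current density shows the classic
#' plate signature: two sharp edge peaks flanking a central plateau.
#'
#' @param e [electrode_spec()]
#' @param voltage applied electrode voltage (V)
#' @param line_standoff_um height of the sampling line above the plate (um)
#' @param x_um sampling positions along the line (um), centred on the plate
#' @param n_patch method-of-moments patches per plate side (>= 20)
#' @return data frame with `x_um`, `j_A_m2` (current-density magnitude),
#'   `j_z_A_m2` (component into the tissue) and `phi_V`
#' @export
plate_current_profile <- function(e, voltage,
                                  line_standoff_um = e$standoff_um,
                                  x_um = seq(-2 * e$side_um, 2 * e$side_um,
                                             by = 2),
                                  n_patch = 24) {
  stopifnot(inherits(e, "electrode_spec"))
  sol <- plate_solution(e, n_patch)
  x <- x_um * 1e-6; z <- line_standoff_um * 1e-6
  jx <- jy <- jz <- numeric(length(x))
  for (j in seq_along(sol$currents)) {
    ddx <- x - sol$centers[j, 1]
    ddy <- -sol$centers[j, 2]
    R3 <- (ddx^2 + ddy^2 + z^2)^1.5
    jx <- jx + sol$currents[j] * ddx / (2 * pi * R3)
    jy <- jy + sol$currents[j] * ddy / (2 * pi * R3)
    jz <- jz + sol$currents[j] * z / (2 * pi * R3)
  }
  phi <- plate_potential_at(sol, e, x, 0, z)
  data.frame(x_um = x_um,
             j_A_m2 = abs(voltage) * sqrt(jx^2 + jy^2 + jz^2),
             j_z_A_m2 = voltage * jz,
             phi_V = voltage * phi)
}

#' Extracellular potential along the axon line per volt of electrode drive
#'
#' @param e [electrode_spec()]
#' @param x_um axial positions (um) along the axon (centred over the plate)
#' @param n_patch method-of-moments patches per side
#' @return numeric vector, potential (V) per 1 V applied
#' @export
plate_potential_line <- function(e, x_um, n_patch = 24) {
  sol <- plate_solution(e, n_patch)
  plate_potential_at(sol, e, x_um * 1e-6, 0, e$standoff_um * 1e-6)
}

# Classical Hodgkin-Huxley rate constants (V in mV, rest at -65).
hh_rates <- function(v) {
  vt <- v + 65
  am <- ifelse(abs(vt - 25) < 1e-7, 1, 0.1 * (25 - vt) / (exp((25 - vt) / 10) - 1))
  bm <- 4 * exp(-vt / 18)
  ah <- 0.07 * exp(-vt / 20)
  bh <- 1 / (exp((30 - vt) / 10) + 1)
  an <- ifelse(abs(vt - 10) < 1e-7, 0.1, 0.01 * (10 - vt) / (exp((10 - vt) / 10) - 1))
  bn <- 0.125 * exp(-vt / 80)
  list(am = am, bm = bm, ah = ah, bh = bh, an = an, bn = bn)
}

#' Hodgkin-Huxley cable simulation under an extracellular field
#'
#' Multi-compartment unmyelinated axon with classical Hodgkin-Huxley
#' membrane kinetics, driven extracellularly: the axial coupling acts on
#' V_i + V_e, so the second spatial difference of the extracellular
#' potential (the activating function) is the source term. Time stepping is
#' operator-split and deterministic: exact exponential gating updates,
#' implicit (tridiagonal) cable solve; sealed ends.
#'
#' @param a [axon_spec()]
#' @param field_profile_V extracellular potential (V) at each compartment
#'   during the pulse plateau (sign included; cathodic drives are negative)
#' @param pulse [stimulus_pulse()]; only the duration is used here - the
#'   amplitude/sign must already be in `field_profile_V`
#' @param dt_ms time step (ms)
#' @param t_end_ms simulation end (ms); default pulse duration + 15 ms
#' @return object of class `membrane_trace`: list with `t_ms`, `x_um` and
#'   matrix `vm_mV` (time x compartment, membrane potential, rest -65 mV)
#' @export
simulate_membrane <- function(a, field_profile_V, pulse, dt_ms = 0.025,
                              t_end_ms = NULL) {
  stopifnot(inherits(a, "axon_spec"), inherits(pulse, "stimulus_pulse"))
  ncomp <- round(a$length_um / a$compartment_um)
  if (length(field_profile_V) != ncomp)
    stop(sprintf("field_profile_V must be sampled at every compartment (need %d values)",
                 ncomp))
  if (dt_ms > 0.1)
    stop("integration step too large for the explicit gating update; use dt_ms <= 0.1")
  if (is.null(t_end_ms)) t_end_ms <- pulse$duration_ms + 15
  nt <- ceiling(t_end_ms / dt_ms)

  # conductances in mS/cm^2, Cm in uF/cm^2, V in mV, t in ms
  gna <- 120; gk <- 36; gl <- 0.3
  ena <- 50; ek <- -77; el <- -54.387; cm <- 1
  d_cm <- a$diameter_um * 1e-4
  dx_cm <- a$compartment_um * 1e-4
  g_ax <- d_cm / (4 * a$axial_resistivity_ohm_cm * dx_cm^2) * 1e3 # mS/cm^2

  v <- rep(-65, ncomp)
  r0 <- hh_rates(-65)
  m <- r0$am / (r0$am + r0$bm)
  h <- r0$ah / (r0$ah + r0$bh)
  n <- r0$an / (r0$an + r0$bn)
  ve_mv <- field_profile_V * 1e3

  lap <- function(u) {
    c(u[2] - u[1], u[-c(1, 2)] - 2 * u[-c(1, ncomp)] + u[-c(ncomp - 1, ncomp)],
      u[ncomp - 1] - u[ncomp])
  }
  ve_drive <- g_ax * lap(ve_mv)

  # constant tridiagonal structure of the implicit cable operator
  off <- rep(-g_ax, ncomp - 1)
  diag_ax <- g_ax * c(1, rep(2, ncomp - 2), 1)

  vm <- matrix(NA_real_, nt + 1, ncomp)
  vm[1, ] <- v
  t_ms <- (0:nt) * dt_ms
  for (it in seq_len(nt)) {
    t_now <- t_ms[it]
    on <- t_now < pulse$duration_ms
    r <- hh_rates(v)
    m <- m + (r$am / (r$am + r$bm) - m) * (1 - exp(-dt_ms * (r$am + r$bm)))
    h <- h + (r$ah / (r$ah + r$bh) - h) * (1 - exp(-dt_ms * (r$ah + r$bh)))
    n <- n + (r$an / (r$an + r$bn) - n) * (1 - exp(-dt_ms * (r$an + r$bn)))
    g_na_t <- gna * m^3 * h; g_k_t <- gk * n^4
    g_tot <- g_na_t + g_k_t + gl
    rhs <- cm / dt_ms * v + g_na_t * ena + g_k_t * ek + gl * el +
      if (on) ve_drive else 0
    dg <- cm / dt_ms + g_tot + diag_ax
    # Thomas algorithm
    cp <- numeric(ncomp - 1); dp <- numeric(ncomp)
    cp[1] <- off[1] / dg[1]; dp[1] <- rhs[1] / dg[1]
    for (i in 2:ncomp) {
      den <- dg[i] - off[i - 1] * cp[i - 1]
      if (i < ncomp) cp[i] <- off[i] / den
      dp[i] <- (rhs[i] - off[i - 1] * dp[i - 1]) / den
    }
    v[ncomp] <- dp[ncomp]
    for (i in (ncomp - 1):1) v[i] <- dp[i] - cp[i] * v[i + 1]
    if (any(!is.finite(v)))
      stop("cable integration diverged; reduce dt_ms")
    vm[it + 1, ] <- v
  }
  structure(list(t_ms = t_ms, x_um = (seq_len(ncomp) - (ncomp + 1) / 2) *
                   a$compartment_um, vm_mV = vm,
                 dt_ms = dt_ms, pulse = pulse),
            class = "membrane_trace")
}

#' @export
print.membrane_trace <- function(x, ...) {
  cat(sprintf(
    "<membrane_trace> %d compartments x %d steps, peak Vm = %.1f mV (rest -65)\n",
    ncol(x$vm_mV), nrow(x$vm_mV), max(x$vm_mV)))
  invisible(x)
}

#' Did the trace contain a propagated action potential?
#'
#' @param trace [simulate_membrane()] result
#' @param threshold_mV spike detection level (membrane potential, mV)
#' @return logical
#' @export
has_spike <- function(trace, threshold_mV = 0) {
  max(trace$vm_mV) > threshold_mV
}

#' Threshold electrode voltage for axon activation
#'
#' Bisection on the cathodic pulse amplitude |V| to 1 mV: the smallest
#' plate voltage magnitude whose extracellular field elicits an action
#' potential in the cable model.
#'
#' @param e [electrode_spec()]
#' @param a [axon_spec()]
#' @param pulse_duration_ms pulse duration (ms)
#' @param dt_ms integration step (ms)
#' @param cap_V search cap on |V| (V); no spike at the cap raises an error
#' @param resolution_V bisection resolution (V)
#' @param n_patch plate patches per side
#' @return threshold voltage magnitude (V); apply cathodic (negative) sign
#'   at the electrode
#' @export
threshold_search <- function(e, a, pulse_duration_ms = 1, dt_ms = 0.025,
                             cap_V = 30, resolution_V = 1e-3,
                             n_patch = 24) {
  stopifnot(inherits(e, "electrode_spec"), inherits(a, "axon_spec"))
  ncomp <- round(a$length_um / a$compartment_um)
  x_um <- (seq_len(ncomp) - (ncomp + 1) / 2) * a$compartment_um
  shape <- plate_potential_line(e, x_um, n_patch)
  spikes <- function(amp) {
    pulse <- stimulus_pulse(-amp, pulse_duration_ms)
    has_spike(simulate_membrane(a, -amp * shape, pulse, dt_ms = dt_ms))
  }
  hi <- 0.05
  while (hi <= cap_V && !spikes(hi)) hi <- hi * 2
  if (hi > cap_V)
    stop(sprintf("no action potential up to the %.1f V amplitude cap", cap_V))
  lo <- if (hi == 0.05) 0 else hi / 2
  while (hi - lo > resolution_V) {
    mid <- (lo + hi) / 2
    if (spikes(mid)) hi <- mid else lo <- mid
  }
  hi
}
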