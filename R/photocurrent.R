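#' Free-carrier generation rate in the active layer
#'
#' G = alpha * lambda * I0 * P / (h c), the volumetric rate of dissociated
#' excitons for an absorption coefficient alpha, incident intensity I0 and
#' dissociation probability P.
#'
#' @param alpha_per_m absorption coefficient (1/m), >= 0
#' @param wavelength_nm wavelength (nm)
#' @param intensity_W_m2 intensity at the layer (W/m^2), >= 0
#' @param p_dissoc exciton dissociation probability in (0, 1]
#' @return generation rate (1/m^3/s)
#' @export
generation_rate <- function(alpha_per_m, wavelength_nm, intensity_W_m2,
                            p_dissoc) {
  stopifnot(all(alpha_per_m >= 0), all(intensity_W_m2 >= 0),
            all(p_dissoc > 0), all(p_dissoc <= 1))
  alpha_per_m * (wavelength_nm * 1e-9) * intensity_W_m2 * p_dissoc /
    pv_constants$hc
}

#' Short-circuit current density of the bare active layer
#'
#' J_sc = G q L with G from [generation_rate()] evaluated at the scenario
#' wavelength and intensity with the bare-blend dissociation probability.
#'
#' @param scenario [device_scenario()]
#' @param cal calibration list
#' @return J_sc (A/m^2)
#' @export
jsc_bare <- function(scenario, cal = pv_calibration()) {
  stopifnot(inherits(scenario, "device_scenario"))
  blend <- cal_fixture(cal, "active_blend")
  lam <- scenario$wavelength_nm
  alpha1 <- absorption_coefficient(nk_at(blend, lam)$k, lam)
  G <- generation_rate(alpha1, lam, intensity_W_m2(scenario$intensity_mW_mm2),
                       scenario$p_bare)
  G * pv_constants$q * scenario$layer_L_nm * 1e-9
}

#' Near-field influence volume ratio of an A-AgNP
#'
#' v1 = Q_abs^(3/2): the near-field absorption region is taken as the
#' sphere whose cross-sectional area equals C_abs, so its volume relative
#' to the particle is (C_abs / pi r^2)^(3/2).
#'
#' @param q_abs_peak peak normalized absorption cross-section, > 0
#' @return dimensionless volume ratio
#' @export
volume_ratio_v1 <- function(q_abs_peak) {
  stopifnot(all(q_abs_peak > 0))
  q_abs_peak^1.5
}

#' Cathode influence volume ratio v2
#'
#' Fraction of the active-layer volume lying within the absorption
#' footprint of the cathode nanoparticles: one K-AgNP per hexagonal lattice
#' site of area (sqrt(3)/2)(2R+d)^2, each projecting its absorption
#' cross-section C_abs over an influence depth into the layer, so
#' v2 = C_abs * L_influence / (site_area * L).
#'
#' @param per_particle_c_abs_nm2 per-particle absorption cross-section
#'   (nm^2), >= 0
#' @param scenario [device_scenario()]
#' @param l_influence_nm influence depth into the active layer (nm);
#'   defaults to the K-AgNP radius
#' @return dimensionless volume ratio
#' @export
volume_ratio_v2 <- function(per_particle_c_abs_nm2, scenario,
                            l_influence_nm = scenario$k_radius_nm) {
  stopifnot(all(per_particle_c_abs_nm2 >= 0))
  site <- sqrt(3) / 2 * (2 * scenario$k_radius_nm + scenario$k_gap_nm)^2
  per_particle_c_abs_nm2 * l_influence_nm / (site * scenario$layer_L_nm)
}

#' Composite short-circuit current density with plasmonic enhancement
#'
#' Three-term photocurrent model:
#' \deqn{J_{sc} = \frac{I_0 \lambda q L}{h c}\left[
#'   P_b \alpha_1 (1 - f_s - v_1 f_s - v_2)
#'   + P_e \alpha_2 (1 - Q_{sc}) v_1 f_s \kappa_A
#'   + k \, P_e \alpha_2 v_2 \kappa_K \right]}
#' with bulk generation in the undisturbed blend (first term), near-field
#' enhanced generation around the A-AgNPs (second term, absorption channel
#' only: the scattered fraction Q_sc is excluded), and generation in the
#' cathode-adjacent region fed by the light the K-AgNPs absorb (third term,
#' weighted by k = T_r x A_b). alpha_1 is the blend absorption coefficient,
#' alpha_2 the metallic absorption coefficient 4 pi k_Ag / lambda; kappa_A
#' and kappa_K are one-point calibration constants frozen in the packaged
#' calibration (the model prose fixes the structure but not the absolute
#' scale of terms 2-3; see the vignette).
#'
#' @param scenario [device_scenario()]
#' @param cal calibration list
#' @param a_b_mode source for the cathode absorptance A_b:
#'   `"reference_table"` (default) or `"coupled_dipole"`
#' @return object of class `jsc_breakdown` with the total and the three
#'   terms (A/m^2) plus all dimensionless intermediates
#' @export
jsc_composite <- function(scenario, cal = pv_calibration(),
                          a_b_mode = "reference_table") {
  stopifnot(inherits(scenario, "device_scenario"))
  lam <- scenario$wavelength_nm
  f_s <- scenario$fill_fraction
  blend <- cal_fixture(cal, "active_blend")
  silver <- cal_fixture(cal, "silver")

  B <- pv_constants$q * (scenario$layer_L_nm * 1e-9) * (lam * 1e-9) *
    intensity_W_m2(scenario$intensity_mW_mm2) / pv_constants$hc
  alpha1 <- absorption_coefficient(nk_at(blend, lam)$k, lam)
  alpha2 <- absorption_coefficient(nk_at(silver, lam)$k, lam)

  use_a <- scenario$include_a_term && f_s > 0
  v1 <- 0; q_sc <- 0
  if (use_a) {
    p <- particle_spec(scenario$a_radius_nm, metal = silver, medium = blend)
    s <- cross_sections(p, 300:800)
    v1 <- volume_ratio_v1(max(s$q_abs))
    q_sc <- scattering_efficiency(s, lam)
  }

  use_k <- scenario$include_k_term
  v2 <- 0; a_b <- NA_real_; t_r <- NA_real_; k_coeff <- 0
  if (use_k) {
    v2 <- volume_ratio_v2(cal$photocurrent$k_c_abs_nm2, scenario,
                          cal$photocurrent$l_influence_nm)
    arr <- array_spec(scenario$k_radius_nm, scenario$k_gap_nm,
                      medium = cal_fixture(cal, "water"))
    a_b <- ab_at(arr, lam, mode = a_b_mode)
    t_r <- total_transmittance(scenario, cal)$t_total
    k_coeff <- t_r * a_b
  }

  frac_bare <- 1 - f_s - v1 * f_s - v2
  if (frac_bare < 0)
    stop(sprintf(paste0(
      "bare-layer absorber fraction is negative (%.3f): the filling ",
      "fraction/influence-volume combination exceeds the layer volume"),
      frac_bare))

  term_bare <- B * scenario$p_bare * alpha1 * frac_bare
  term_a <- if (use_a)
    B * scenario$p_enhanced * alpha2 * (1 - q_sc) * v1 * f_s *
      cal$photocurrent$kappa_A else 0
  term_k <- if (use_k)
    B * scenario$p_enhanced * alpha2 * v2 * k_coeff *
      cal$photocurrent$kappa_K else 0

  structure(list(
    wavelength_nm = lam, jsc_total = term_bare + term_a + term_k,
    term_bare = term_bare, term_a_np = term_a, term_k_np = term_k,
    v1 = v1, v2 = v2, k_coeff = k_coeff, q_sc = q_sc,
    t_r = t_r, a_b = a_b, alpha1_per_m = alpha1, alpha2_per_m = alpha2,
    frac_bare = frac_bare, scenario = scenario
  ), class = "jsc_breakdown")
}

#' @export
print.jsc_breakdown <- function(x, ...) {
  cat("<jsc_breakdown>\n")
  cat(sprintf("  J_sc total : %.2f A/m^2 at %g nm\n", x$jsc_total,
              x$wavelength_nm))
  cat(sprintf("  bulk term  : %.2f A/m^2 (absorber fraction %.3f)\n",
              x$term_bare, x$frac_bare))
  cat(sprintf("  A-NP term  : %.2f A/m^2 (v1 %.3f, Q_sc %.4f)\n",
              x$term_a_np, x$v1, x$q_sc))
  cat(sprintf("  K-NP term  : %.2f A/m^2 (v2 %.3f, k = T_r x A_b = %.3f)\n",
              x$term_k_np, x$v2, x$k_coeff))
  invisible(x)
}
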