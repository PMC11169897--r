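# Package-level cache for fixtures and the frozen calibration.
.pv_env <- new.env(parent = emptyenv())

#' Clear the in-memory fixture/calibration cache
#' @return invisibly, TRUE
#' @export
pv_cache_clear <- function() {
  rm(list = ls(.pv_env), envir = .pv_env)
  invisible(TRUE)
}

# Fixture accessor honouring in-memory fixtures carried by a calibration
# list (used while the calibration itself is being computed, before any
# fixture file exists); falls back to the packaged tables, cached.
cal_fixture <- function(cal, material) {
  if (!is.null(cal$fixtures) && !is.null(cal$fixtures[[material]]))
    return(cal$fixtures[[material]])
  key <- paste0("fixture_", material)
  if (is.null(.pv_env[[key]]))
    .pv_env[[key]] <- load_optical_constants(material)
  .pv_env[[key]]
}

#' The frozen packaged calibration
#'
#' Loads (and caches) the calibration constants shipped in
#' `inst/extdata/calibration.yaml`: the fixture model parameters, the two
#' attenuation conventions, the photocurrent scale factors kappa_A/kappa_K,
#' the cathode influence-volume convention, and the electrode-interface
#' defaults. Runs never refit silently; [compute_calibration()] regenerates
#' the same numbers from the anchor values.
#'
#' @return nested calibration list
#' @export
pv_calibration <- function() {
  if (is.null(.pv_env$calibration)) {
    path <- system.file("extdata", "calibration.yaml", package = "plasmopv",
                        mustWork = TRUE)
    .pv_env$calibration <- yaml::read_yaml(path)
  }
  .pv_env$calibration
}

# Published anchor values the calibration is pinned to (device-level
# characteristics of the modelled pixel). Everything else the package
# reports is predicted, not fitted.
pv_anchors <- list(
  jsc_bare_453_A_m2 = 7.5,    # bare layer, 453 nm, 0.26 mW/mm^2
  jsc_bare_250_A_m2 = 19,     # bare layer, 250 nm, 0.26 mW/mm^2
  q_abs_peak_r10 = 2.4,       # peak Q_abs, r = 10 nm in the blend
  t_np_f10 = 0.946,           # A-AgNP transmittance, f_s = 10%, 453 nm
  t_layer_f075 = 0.57,        # bare-layer transmittance, f_s = 7.5%, 453 nm
  jsc_r5_f5_withK_A_m2 = 15,  # kappa_A anchor (r=5, f_s=5%, 0.26, with K)
  jsc_r75_f10_withK_033 = 36, # kappa_K anchor pair (r=7.5, f_s=10%, 0.33)
  jsc_r75_f10_noK_033 = 33
)

# Analytic material models used during calibration (identical in content to
# the synthesize_* table builders, but pointwise and smooth in the
# parameters, which the root finders need).
drude_eps <- function(wavelength_nm, eps_inf, hw_p_eV, gamma_eV) {
  E <- pv_constants$eV_nm / wavelength_nm
  eps_inf - hw_p_eV^2 / (E^2 + 1i * gamma_eV * E)
}

blend_k_gauss <- function(wavelength_nm, k_uv, k_vis, b) {
  k_uv * exp(-((wavelength_nm - b$uv_center_nm) / b$uv_width_nm)^2) +
    k_vis * exp(-((wavelength_nm - b$vis_center_nm) / b$vis_width_nm)^2)
}

#' Recompute the full calibration from its anchors
#'
#' Deterministic chain (all root finds are 1-D bracketed bisections on
#' smooth functions):
#' 1. Blend extinction k(453)/k(250) from the bare-layer photocurrent
#'    anchors via J_sc = (q L lambda I0 / h c) P alpha_1; the two Gaussian
#'    band amplitudes solve a 2x2 linear system.
#' 2. Silver Drude damping gamma and blend Cauchy offset A jointly so that
#'    (a) the quasi-static absorption peak of an r = 10 nm sphere in the
#'    blend sits exactly at 453 nm and (b) its peak Q_abs equals 2.4.
#' 3. A-AgNP channel concentration coupling kappa_np from the 94.6%
#'    transmittance anchor; layer effective path from the 57% anchor.
#' 4. kappa_K from one with/without-cathode photocurrent pair, then
#'    kappa_A from one single-point photocurrent anchor.
#'
#' @param grid_nm wavelength grid for the generated fixture tables
#' @return calibration list (with in-memory `fixtures` attached)
#' @export
compute_calibration <- function(grid_nm = 250:800) {
  cn <- pv_constants
  L_m <- 70e-9
  blend_shape <- list(cauchy_B_nm2 = 4e4, uv_center_nm = 250,
                      uv_width_nm = 120, vis_center_nm = 500,
                      vis_width_nm = 180)
  silver_fixed <- list(eps_inf = 3.7, hw_p_eV = 9.01)

  # -- 1. blend extinction anchors ----------------------------------------
  k_from_jsc <- function(jsc, lam_nm, intensity_W) {
    alpha1 <- jsc * cn$hc / (0.7 * cn$q * L_m * (lam_nm * 1e-9) * intensity_W)
    alpha1 * (lam_nm * 1e-9) / (4 * pi)
  }
  k453 <- k_from_jsc(pv_anchors$jsc_bare_453_A_m2, 453, 260)
  k250 <- k_from_jsc(pv_anchors$jsc_bare_250_A_m2, 250, 260)
  g <- function(lam, ctr, w) exp(-((lam - ctr) / w)^2)
  M <- rbind(
    c(g(453, 250, 120), g(453, 500, 180)),
    c(g(250, 250, 120), g(250, 500, 180)))
  amps <- solve(M, c(k453, k250))
  k_uv <- amps[1]; k_vis <- amps[2]
  stopifnot(k_uv > 0, k_vis > 0)

  # -- 2. silver damping + blend index ------------------------------------
  imF_times_invlam <- function(lam, gamma, cauchy_A) {
    eps_m <- drude_eps(lam, silver_fixed$eps_inf, silver_fixed$hw_p_eV, gamma)
    n_s <- cauchy_A + blend_shape$cauchy_B_nm2 / lam^2
    k_s <- blend_k_gauss(lam, k_uv, k_vis, blend_shape)
    eps_s <- (complex(real = n_s, imaginary = k_s))^2
    Im((eps_m - eps_s) / (eps_m + 2 * eps_s)) / lam
  }
  solve_A_for_peak <- function(gamma) {
    # centre the absorption peak at 453 nm: d/dlambda of Im F / lambda = 0
    slope <- function(A) {
      (imF_times_invlam(453.5, gamma, A) -
         imF_times_invlam(452.5, gamma, A))
    }
    stats::uniroot(slope, c(1.2, 2.4), tol = 1e-12)$root
  }
  q_abs_at_453 <- function(gamma, A, r = 10) {
    V <- 4 / 3 * pi * r^3
    (2 * pi) * 3 * V * imF_times_invlam(453, gamma, A) / (pi * r^2)
  }
  gamma_gap <- function(gamma) {
    A <- solve_A_for_peak(gamma)
    q_abs_at_453(gamma, A) - pv_anchors$q_abs_peak_r10
  }
  gamma <- stats::uniroot(gamma_gap, c(0.05, 2.5), tol = 1e-10)$root
  cauchy_A <- solve_A_for_peak(gamma)

  cal <- list(
    silver = c(silver_fixed, list(gamma_eV = gamma)),
    blend = c(list(cauchy_A = cauchy_A), blend_shape,
              list(k_uv = k_uv, k_vis = k_vis)),
    anchors = pv_anchors
  )
  cal$fixtures <- fixture_set(cal, grid_nm)

  # -- 3. attenuation conventions -----------------------------------------
  alpha1_453 <- absorption_coefficient(
    nk_at(cal$fixtures$active_blend, 453)$k, 453)
  cal$attenuation <- list(
    layer_path_nm = -log(pv_anchors$t_layer_f075) /
      (alpha1_453 * (1 - 0.075)) * 1e9,
    kappa_np = 1
  )
  sc10 <- device_scenario(a_radius_nm = 10, fill_fraction = 0.10)
  a_unit <- total_transmittance(sc10, cal)$absorbance_np
  cal$attenuation$kappa_np <- -log10(pv_anchors$t_np_f10) / a_unit

  # -- 4. photocurrent scale factors --------------------------------------
  cal$photocurrent <- list(k_c_abs_nm2 = 1500, l_influence_nm = 25,
                           kappa_A = 1, kappa_K = 1)
  sc_w <- device_scenario(a_radius_nm = 7.5, fill_fraction = 0.10,
                          intensity_mW_mm2 = 0.33)
  sc_wo <- device_scenario(a_radius_nm = 7.5, fill_fraction = 0.10,
                           intensity_mW_mm2 = 0.33, include_k_term = FALSE)
  bw <- jsc_composite(sc_w, cal)
  bwo <- jsc_composite(sc_wo, cal)
  d_target <- pv_anchors$jsc_r75_f10_withK_033 - pv_anchors$jsc_r75_f10_noK_033
  cal$photocurrent$kappa_K <-
    (d_target - (bw$term_bare - bwo$term_bare)) / bw$term_k_np

  sc_a <- device_scenario(a_radius_nm = 5, fill_fraction = 0.05)
  ba <- jsc_composite(sc_a, cal)  # kappa_K already in effect, kappa_A still 1
  cal$photocurrent$kappa_A <-
    (pv_anchors$jsc_r5_f5_withK_A_m2 - ba$term_bare - ba$term_k_np) /
    ba$term_a_np

  # -- 5. electrode-interface defaults ------------------------------------
  cal$electrode <- list(z_interface_ohm_m2 = 4.3e-3,
                        j_threshold_A_m2 = 25.1)
  cal
}

#' Write the packaged calibration file and fixture tables
#'
#' Regenerates `calibration.yaml` and the three `*_nk.tsv` fixture tables
#' under `dir` from [compute_calibration()].
#'
#' @param dir target directory (normally `inst/extdata` of the source tree)
#' @return the calibration list, invisibly
#' @export
build_calibration_file <- function(dir) {
  stopifnot(dir.exists(dir))
  cal <- compute_calibration()
  out <- cal[c("silver", "blend", "attenuation", "photocurrent",
               "electrode", "anchors")]
  yaml::write_yaml(out, file.path(dir, "calibration.yaml"),
                   precision = 15)
  build_fixture_tables(dir, cal)
  invisible(cal)
}
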