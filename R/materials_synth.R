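#' Parametric optical-constant models behind the packaged fixtures
#'
#' The three fixture tables shipped under `inst/extdata` are generated by
#' these functions, with parameter values frozen in the packaged calibration
#' file (see [pv_calibration()]). The silver table follows a Drude form
#' `eps(E) = eps_inf - wp^2 / (E^2 + i*gamma*E)` whose damping is calibrated
#' against the device-level absorption anchors; the blend combines a Cauchy
#' refractive index with a two-Gaussian extinction band (a UV band centred at
#' 250 nm, a visible shoulder centred at 500 nm); water is dispersionless
#' (n = 1.33, k = 0). See the methods vignette for why and how each
#' parameter is pinned.
#'
#' @param wavelengths_nm wavelength grid (nm)
#' @param eps_inf high-frequency permittivity offset of the metal
#' @param hw_p_eV plasma energy (eV)
#' @param gamma_eV damping energy (eV)
#' @return [optical_constants()] table
#' @name materials-synth
NULL

#' @rdname materials-synth
#' @export
synthesize_silver_nk <- function(wavelengths_nm = 250:800,
                                 eps_inf = 3.7, hw_p_eV = 9.01,
                                 gamma_eV = 0.5) {
  E <- pv_constants$eV_nm / wavelengths_nm
  eps <- eps_inf - hw_p_eV^2 / (E^2 + 1i * gamma_eV * E)
  nk <- eps_to_nk(eps)
  optical_constants("silver", wavelengths_nm, nk$n, nk$k)
}

#' @rdname materials-synth
#' @param cauchy_A,cauchy_B_nm2 Cauchy coefficients of the blend index,
#'   n(lambda) = A + B / lambda^2
#' @param k_uv,k_vis Gaussian extinction amplitudes of the blend
#' @param uv_center_nm,uv_width_nm,vis_center_nm,vis_width_nm Gaussian band
#'   positions/widths (nm)
#' @export
synthesize_blend_nk <- function(wavelengths_nm = 250:800,
                                cauchy_A = 1.65, cauchy_B_nm2 = 4e4,
                                k_uv = 0.14, k_vis = 0.054,
                                uv_center_nm = 250, uv_width_nm = 120,
                                vis_center_nm = 500, vis_width_nm = 180) {
  n <- cauchy_A + cauchy_B_nm2 / wavelengths_nm^2
  k <- k_uv * exp(-((wavelengths_nm - uv_center_nm) / uv_width_nm)^2) +
    k_vis * exp(-((wavelengths_nm - vis_center_nm) / vis_width_nm)^2)
  optical_constants("active_blend", wavelengths_nm, n, k)
}

#' @rdname materials-synth
#' @export
synthesize_water_nk <- function(wavelengths_nm = 250:800) {
  optical_constants("water", wavelengths_nm,
                    rep(1.33, length(wavelengths_nm)),
                    rep(0, length(wavelengths_nm)))
}

#' Complex permittivity to (n, k)
#'
#' Principal square root of eps; n > 0, k >= 0 for physical media.
#'
#' @param eps complex permittivity vector
#' @return list with numeric vectors `n`, `k`
#' @export
eps_to_nk <- function(eps) {
  m <- sqrt(eps)
  list(n = Re(m), k = Im(m))
}

#' Regenerate the packaged fixture tables from frozen parameters
#'
#' Writes `silver_nk.tsv`, `active_blend_nk.tsv` and `water_nk.tsv` into
#' `dir` using the parameter values in `cal` (defaulting to the packaged
#' calibration). Used to build the shipped fixtures and by the test suite to
#' confirm the shipped files match the frozen parameters.
#'
#' @param dir output directory
#' @param cal calibration list, see [pv_calibration()]
#' @return character vector of written paths, invisibly
#' @export
build_fixture_tables <- function(dir, cal = pv_calibration()) {
  stopifnot(dir.exists(dir))
  grid <- 250:800
  fx <- fixture_set(cal, grid)
  paths <- vapply(names(fx), function(m) {
    write_optical_constants(fx[[m]], file.path(dir, paste0(m, "_nk.tsv")))
    file.path(dir, paste0(m, "_nk.tsv"))
  }, character(1))
  invisible(paths)
}

# Build the three fixture tables in memory from a calibration list.
fixture_set <- function(cal, wavelengths_nm = 250:800) {
  s <- cal$silver
  b <- cal$blend
  list(
    silver = synthesize_silver_nk(wavelengths_nm, s$eps_inf, s$hw_p_eV,
                                  s$gamma_eV),
    active_blend = synthesize_blend_nk(
      wavelengths_nm, b$cauchy_A, b$cauchy_B_nm2, b$k_uv, b$k_vis,
      b$uv_center_nm, b$uv_width_nm, b$vis_center_nm, b$vis_width_nm),
    water = synthesize_water_nk(wavelengths_nm)
  )
}
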