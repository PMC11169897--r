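#' Device scenario: one full pixel configuration
#'
#' Bundles every knob of the modelled photovoltaic pixel: geometry of the
#' silver nanospheres embedded in the active layer (A-AgNPs: radius `r`,
#' volume filling fraction `f_s`), geometry of the cathode nanoparticle
#' monolayer (K-AgNPs: radius `R`, interparticle gap `d`), illumination
#' (wavelength, intensity), active-layer geometry, and the exciton
#' dissociation probabilities for bare and nanoparticle-adjacent blend.
#'
#' @param a_radius_nm A-AgNP radius r (nm); studied values 5, 7.5, 10
#' @param fill_fraction A-AgNP volume filling fraction f_s in (0, 0.10]
#' @param k_radius_nm K-AgNP radius R (nm); 25 in the studied device
#' @param k_gap_nm K-AgNP interparticle gap d (nm); studied values 1, 1.5,
#'   2.5, 5
#' @param intensity_mW_mm2 incident intensity (mW/mm^2); studied values
#'   0.26, 0.33
#' @param wavelength_nm illumination wavelength (nm); 453 (plasmon
#'   resonance) or 250 (bare-blend absorption optimum)
#' @param layer_L_nm active-layer thickness L (nm)
#' @param donor_W_nm,acceptor_W_nm donor/acceptor domain widths of the comb
#'   morphology (nm); configuration constants, not used by the optical chain
#' @param cell_side_um pixel (and electrode) side length (um); the cell area
#'   is `cell_side_um^2`
#' @param p_bare exciton dissociation probability of the bare blend
#' @param p_enhanced dissociation probability near A-AgNPs and K-AgNPs
#' @param include_k_term include the cathode-absorption photocurrent term
#'   (requires K-AgNPs present)
#' @param include_a_term include the A-AgNP near-field photocurrent term
#' @return object of class `device_scenario` (named list)
#' @export
device_scenario <- function(a_radius_nm = 10, fill_fraction = 0.10,
                            k_radius_nm = 25, k_gap_nm = 1.5,
                            intensity_mW_mm2 = 0.26, wavelength_nm = 453,
                            layer_L_nm = 70, donor_W_nm = 14,
                            acceptor_W_nm = 25, cell_side_um = 100,
                            p_bare = 0.7, p_enhanced = 0.85,
                            include_k_term = TRUE, include_a_term = TRUE) {
  sc <- list(a_radius_nm = a_radius_nm, fill_fraction = fill_fraction,
             k_radius_nm = k_radius_nm, k_gap_nm = k_gap_nm,
             intensity_mW_mm2 = intensity_mW_mm2,
             wavelength_nm = wavelength_nm, layer_L_nm = layer_L_nm,
             donor_W_nm = donor_W_nm, acceptor_W_nm = acceptor_W_nm,
             cell_side_um = cell_side_um, p_bare = p_bare,
             p_enhanced = p_enhanced,
             include_k_term = isTRUE(include_k_term),
             include_a_term = isTRUE(include_a_term))
  validate_scenario(sc)
}

validate_scenario <- function(sc) {
  num_pos <- c("a_radius_nm", "k_radius_nm", "k_gap_nm", "intensity_mW_mm2",
               "wavelength_nm", "layer_L_nm", "donor_W_nm", "acceptor_W_nm",
               "cell_side_um")
  for (f in num_pos) {
    v <- sc[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("scenario field '%s' must be a positive number", f))
  }
  if (!is.numeric(sc$fill_fraction) || sc$fill_fraction < 0 ||
      sc$fill_fraction > 0.10)
    stop("fill_fraction must lie in [0, 0.10]; loadings above 10% damage the active layer and are outside the model's validity")
  for (f in c("p_bare", "p_enhanced")) {
    v <- sc[[f]]
    if (!is.numeric(v) || v <= 0 || v > 1)
      stop(sprintf("scenario field '%s' must lie in (0, 1]", f))
  }
  if (sc$a_radius_nm > 50)
    stop("a_radius_nm must be <= 50 nm (quasi-static validity domain)")
  class(sc) <- "device_scenario"
  sc
}

#' @export
print.device_scenario <- function(x, ...) {
  cat(sprintf(
    "<device_scenario> r=%g nm, f_s=%g%%, K: R=%g nm d=%g nm | %g nm @ %g mW/mm^2 | terms: A=%s K=%s\n",
    x$a_radius_nm, 100 * x$fill_fraction, x$k_radius_nm, x$k_gap_nm,
    x$wavelength_nm, x$intensity_mW_mm2,
    x$include_a_term, x$include_k_term))
  invisible(x)
}

#' Read a device scenario from a YAML configuration file
#'
#' Keys mirror the arguments of [device_scenario()]; unknown keys raise an
#' error, missing keys take the defaults.
#'
#' @param path YAML file path
#' @return `device_scenario`
#' @export
read_scenario <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(device_scenario))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown scenario field(s): ", paste(bad, collapse = ", "))
  do.call(device_scenario, vals)
}

#' Built-in scenarios of the study
#'
#' `scenario_preferred()` is the headline configuration (r = 10 nm,
#' f_s = 10%, K-AgNPs R = 25 nm / d = 1.5 nm, 453 nm at 0.26 mW/mm^2);
#' `scenario_bare()` is the same pixel without any nanoparticles.
#'
#' @param wavelength_nm illumination wavelength for the bare scenario
#' @param intensity_mW_mm2 incident intensity
#' @return `device_scenario`
#' @export
scenario_preferred <- function(intensity_mW_mm2 = 0.26) {
  device_scenario(a_radius_nm = 10, fill_fraction = 0.10,
                  intensity_mW_mm2 = intensity_mW_mm2)
}

#' @rdname scenario_preferred
#' @export
scenario_bare <- function(wavelength_nm = 453, intensity_mW_mm2 = 0.26) {
  device_scenario(a_radius_nm = 10, fill_fraction = 0,
                  wavelength_nm = wavelength_nm,
                  intensity_mW_mm2 = intensity_mW_mm2,
                  include_k_term = FALSE, include_a_term = FALSE)
}
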