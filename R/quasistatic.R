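#' Metal nanosphere in a host medium (quasi-static dipole limit)
#'
#' @param radius_nm sphere radius r (nm); must be <= 50 nm, the size range
#'   where the particle responds as a single electric dipole
#' @param metal material label (see [load_optical_constants()]) or an
#'   [optical_constants()] table for the particle metal
#' @param medium material label or table for the surrounding medium
#' @return object of class `particle_spec`
#' @export
particle_spec <- function(radius_nm, metal = "silver",
                          medium = "active_blend") {
  stopifnot(is.numeric(radius_nm), length(radius_nm) == 1L, radius_nm > 0)
  if (radius_nm > 50)
    stop("quasi-static treatment is limited to radius <= 50 nm")
  as_oc <- function(x) {
    if (inherits(x, "optical_constants")) x else load_optical_constants(x)
  }
  structure(list(radius_nm = radius_nm,
                 metal = as_oc(metal), medium = as_oc(medium),
                 volume_nm3 = 4 / 3 * pi * radius_nm^3),
            class = "particle_spec")
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf("<particle_spec> r=%g nm, %s in %s\n", x$radius_nm,
              attr(x$metal, "material"), attr(x$medium, "material")))
  invisible(x)
}

#' Quasi-static dipole polarizability of a nanosphere
#'
#' alpha_sp = 3 V (eps_m - eps_s) / (eps_m + 2 eps_s), a complex volume in
#' nm^3. Diverges toward the Froehlich condition Re(eps_m + 2 eps_s) -> 0,
#' which locates the localized surface plasmon resonance.
#'
#' @param p [particle_spec()]
#' @param wavelength_nm wavelength(s) in nm, within the fixture range
#' @return complex polarizability (nm^3), vectorized over wavelength
#' @export
polarizability <- function(p, wavelength_nm) {
  stopifnot(inherits(p, "particle_spec"))
  eps_m <- permittivity(p$metal, wavelength_nm)
  eps_s <- permittivity(p$medium, wavelength_nm)
  3 * p$volume_nm3 * (eps_m - eps_s) / (eps_m + 2 * eps_s)
}

#' Absorption and scattering cross-section spectra
#'
#' Evaluates `C_abs = (2 pi / lambda) Im(alpha_sp)` and
#' `C_scat = (1 / 6 pi) (2 pi / lambda)^4 |alpha_sp|^2` over a wavelength
#' grid, together with the normalized efficiencies
#' `Q_abs = C_abs / (pi r^2)`, `Q_scat = C_scat / (pi r^2)` and the
#' scattering efficiency `Q_sc = C_scat / (C_scat + C_abs)`.
#'
#' By default `lambda` is the vacuum wavelength; `medium_wavelength = TRUE`
#' switches both prefactors to the in-medium wavelength `lambda / n_s` (see
#' the methods vignette for why vacuum is the default).
#'
#' @param p [particle_spec()]
#' @param wavelengths_nm wavelength grid (nm), non-empty, within fixture range
#' @param medium_wavelength logical; use lambda / n_s in the prefactors
#' @return object of class `cross_section_spectrum`: a data frame with
#'   columns `wavelength_nm`, `c_abs_nm2`, `c_scat_nm2`, `q_abs`, `q_scat`,
#'   `q_sc`
#' @export
cross_sections <- function(p, wavelengths_nm, medium_wavelength = FALSE) {
  stopifnot(inherits(p, "particle_spec"))
  if (length(wavelengths_nm) == 0L)
    stop("empty wavelength grid")
  alpha <- polarizability(p, wavelengths_nm)
  lam <- wavelengths_nm
  if (medium_wavelength)
    lam <- lam / nk_at(p$medium, wavelengths_nm)$n
  kfac <- 2 * pi / lam
  c_abs <- kfac * Im(alpha)
  c_scat <- kfac^4 / (6 * pi) * Mod(alpha)^2
  geo <- pi * p$radius_nm^2
  tot <- c_scat + c_abs
  q_sc <- ifelse(tot > 0, c_scat / tot, NA_real_)
  out <- data.frame(wavelength_nm = wavelengths_nm,
                    c_abs_nm2 = c_abs, c_scat_nm2 = c_scat,
                    q_abs = c_abs / geo, q_scat = c_scat / geo,
                    q_sc = q_sc)
  attr(out, "particle") <- p
  attr(out, "medium_wavelength") <- medium_wavelength
  class(out) <- c("cross_section_spectrum", "data.frame")
  out
}

#' Scattering efficiency at a wavelength
#'
#' Q_sc = C_scat / (C_scat + C_abs), the fraction of the extinguished power
#' that is re-radiated rather than absorbed; always in [0, 1]. Cross
#' sections are linearly interpolated on the spectrum grid.
#'
#' @param s [cross_sections()] spectrum
#' @param wavelength_nm query wavelength (nm), within the spectrum grid
#' @return dimensionless efficiency in [0, 1]
#' @export
scattering_efficiency <- function(s, wavelength_nm) {
  stopifnot(inherits(s, "cross_section_spectrum"))
  rng <- range(s$wavelength_nm)
  if (any(wavelength_nm < rng[1] | wavelength_nm > rng[2]))
    stop("wavelength outside the spectrum grid")
  ca <- stats::approx(s$wavelength_nm, s$c_abs_nm2, xout = wavelength_nm)$y
  cs <- stats::approx(s$wavelength_nm, s$c_scat_nm2, xout = wavelength_nm)$y
  if (any(ca + cs <= 0))
    stop("scattering efficiency undefined: C_scat + C_abs is zero at the requested wavelength")
  cs / (cs + ca)
}

#' Locate the localized surface plasmon resonance on a wavelength grid
#'
#' Returns the grid wavelength maximizing C_abs. The maximum must be
#' bracketed: a maximum on the first or last grid point raises an error.
#' Ties break toward the shorter wavelength.
#'
#' @param p [particle_spec()]
#' @param wavelengths_nm search grid (nm); default 1-nm steps over 300-800
#' @param medium_wavelength passed to [cross_sections()]
#' @return resonance wavelength (nm)
#' @export
find_lspr <- function(p, wavelengths_nm = 300:800,
                      medium_wavelength = FALSE) {
  s <- cross_sections(p, wavelengths_nm, medium_wavelength)
  i <- which.max(s$c_abs_nm2)
  if (i == 1L || i == nrow(s))
    stop("resonance not bracketed: C_abs maximal at the grid boundary")
  s$wavelength_nm[i]
}

#' Write a cross-section spectrum as tab-separated text
#'
#' @param s [cross_sections()] spectrum
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_cross_sections <- function(s, path) {
  stopifnot(inherits(s, "cross_section_spectrum"))
  utils::write.table(as.data.frame(s), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
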