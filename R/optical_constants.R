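#' Wavelength-dependent optical constants of a material
#'
#' Container for a tabulated complex refractive index (n + i k) on a strictly
#' increasing wavelength grid. All downstream permittivities (the metal
#' nanoparticle, the PCPDTBT:PCBM host, the water half-space above the
#' cathode) are derived from objects of this class.
#'
#' @param material_name label, e.g. "silver"
#' @param wavelengths_nm strictly increasing wavelength grid (nm); must cover
#'   at least 250-800 nm
#' @param n refractive index per wavelength (> 0)
#' @param k extinction index per wavelength (>= 0)
#' @return An object of class `optical_constants`: a data frame with columns
#'   `wavelength_nm`, `n`, `k` and attribute `material`.
#' @export
optical_constants <- function(material_name, wavelengths_nm, n, k) {
  stopifnot(is.character(material_name), length(material_name) == 1L)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  n <- as.numeric(n)
  k <- as.numeric(k)
  if (length(wavelengths_nm) < 2L)
    stop("optical constants need at least two wavelength points")
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (length(n) != length(wavelengths_nm) || length(k) != length(wavelengths_nm))
    stop("n and k must have one value per wavelength")
  if (min(wavelengths_nm) > 250 || max(wavelengths_nm) < 800)
    stop("optical-constant table must cover at least 250-800 nm")
  if (any(!is.finite(n)) || any(n <= 0)) stop("n must be finite and > 0")
  if (any(!is.finite(k)) || any(k < 0)) stop("k must be finite and >= 0")
  out <- data.frame(wavelength_nm = wavelengths_nm, n = n, k = k)
  attr(out, "material") <- material_name
  class(out) <- c("optical_constants", "data.frame")
  out
}

#' @export
print.optical_constants <- function(x, ...) {
  cat(sprintf("<optical_constants> %s: %d points, %.0f-%.0f nm\n",
              attr(x, "material"), nrow(x),
              min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}

pv_materials <- c("silver", "active_blend", "water")

#' Load a packaged optical-constant fixture
#'
#' Serves the three materials the device model needs: `"silver"` (the
#' nanoparticle metal), `"active_blend"` (the PCPDTBT:PCBM host; calibrated,
#' see the methods vignette) and `"water"` (constant n = 1.33, k = 0).
#'
#' @param material_name one of `"silver"`, `"active_blend"`, `"water"`
#' @return [optical_constants()] table
#' @export
load_optical_constants <- function(material_name) {
  if (!is.character(material_name) || length(material_name) != 1L ||
      !(material_name %in% pv_materials)) {
    stop(sprintf("unknown material '%s'; available: %s",
                 as.character(material_name)[1],
                 paste(pv_materials, collapse = ", ")))
  }
  path <- system.file("extdata", paste0(material_name, "_nk.tsv"),
                      package = "plasmopv", mustWork = TRUE)
  read_optical_constants(path, material_name)
}

#' Read an optical-constant table from a delimited text file
#'
#' Expects a header row with columns `wavelength_nm`, `n`, `k` (tab- or
#' whitespace-separated).
#'
#' @param path file path
#' @param material_name label to attach; defaults to the file stem
#' @return [optical_constants()] table
#' @export
read_optical_constants <- function(path, material_name = NULL) {
  tab <- utils::read.table(path, header = TRUE)
  need <- c("wavelength_nm", "n", "k")
  if (!all(need %in% names(tab)))
    stop("optical-constant file must have columns wavelength_nm, n, k")
  if (is.null(material_name))
    material_name <- sub("_nk$", "", tools::file_path_sans_ext(basename(path)))
  optical_constants(material_name, tab$wavelength_nm, tab$n, tab$k)
}

#' Write an optical-constant table as tab-separated text
#'
#' Full double precision is kept so a write/read round trip is bit-exact.
#'
#' @param oc [optical_constants()] table
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_optical_constants <- function(oc, path) {
  stopifnot(inherits(oc, "optical_constants"))
  df <- data.frame(wavelength_nm = format(oc$wavelength_nm, digits = 17),
                   n = format(oc$n, digits = 17),
                   k = format(oc$k, digits = 17))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Interpolated n and k at arbitrary wavelengths
#'
#' Linear interpolation in n and k (not in permittivity); no extrapolation
#' beyond the table range.
#'
#' @param oc [optical_constants()] table
#' @param wavelength_nm wavelength(s) in nm, inside the table range
#' @return list with numeric vectors `n` and `k`
#' @export
nk_at <- function(oc, wavelength_nm) {
  stopifnot(inherits(oc, "optical_constants"))
  rng <- range(oc$wavelength_nm)
  if (any(wavelength_nm < rng[1] | wavelength_nm > rng[2]))
    stop(sprintf("wavelength outside the %s table range [%g, %g] nm; no extrapolation",
                 attr(oc, "material"), rng[1], rng[2]))
  list(
    n = stats::approx(oc$wavelength_nm, oc$n, xout = wavelength_nm)$y,
    k = stats::approx(oc$wavelength_nm, oc$k, xout = wavelength_nm)$y
  )
}

#' Complex relative permittivity at a wavelength
#'
#' eps = (n + i k)^2 with n, k linearly interpolated at the requested
#' wavelength.
#'
#' @inheritParams nk_at
#' @return complex vector of relative permittivities
#' @export
permittivity <- function(oc, wavelength_nm) {
  nk <- nk_at(oc, wavelength_nm)
  (complex(real = nk$n, imaginary = nk$k))^2
}
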