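# Regenerates the packaged fixture tables and the frozen calibration file
# from the anchor values in R/calibration.R. Run from the package root:
#   Rscript data-raw/build_fixtures.R
devtools::load_all(".", quiet = TRUE)
cal <- build_calibration_file("inst/extdata")
cat("silver gamma_eV:", cal$silver$gamma_eV, "\n")
cat("blend cauchy_A:", cal$blend$cauchy_A, "\n")
cat("kappa_np:", cal$attenuation$kappa_np,
    "layer_path_nm:", cal$attenuation$layer_path_nm, "\n")
cat("kappa_A:", cal$photocurrent$kappa_A,
    "kappa_K:", cal$photocurrent$kappa_K, "\n")
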