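# Shared helpers for the suite: flat (dispersionless) optical-constant
# tables for constructed-oracle tests, and the studied scenario grid.

flat_material <- function(name, n, k = 0, grid = c(250, 500, 800)) {
  optical_constants(name, grid, rep(n, length(grid)), rep(k, length(grid)))
}

# All printed short-circuit current grids of the study, used by the
# photocurrent tests and the acceptance suite. Columns: radius, filling
# fraction, intensity, with/without cathode particles, printed J_sc.
printed_jsc_grid <- function() {
  rbind(
    data.frame(r = 5,   f = c(.05, .075, .10), i = .26, k = TRUE,  jsc = c(15, 17, 20)),
    data.frame(r = 7.5, f = c(.05, .075, .10), i = .26, k = TRUE,  jsc = c(20, 24, 29)),
    data.frame(r = 10,  f = c(.05, .075, .10), i = .26, k = TRUE,  jsc = c(25, 32, 39)),
    data.frame(r = 10,  f = c(.05, .075, .10), i = .26, k = FALSE, jsc = c(23, 29, 36)),
    data.frame(r = 7.5, f = c(.05, .075, .10), i = .33, k = TRUE,  jsc = c(25, 30, 36)),
    data.frame(r = 7.5, f = c(.05, .075, .10), i = .33, k = FALSE, jsc = c(22, 27, 33))
  )
}

grid_scenario <- function(row) {
  device_scenario(a_radius_nm = row$r, fill_fraction = row$f,
                  intensity_mW_mm2 = row$i, include_k_term = row$k)
}
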