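# Shared fixtures: the shipped coefficient library (loaded once), toy
# power-law tables, and small hand-built spectra.

TABS <- default_coefficients()

# spectrum with a single occupied bin at energy E (built on a short grid so
# the 0.5 keV spacing invariant holds)
mono_spectrum <- function(E, counts = 1, voltage = NA_real_) {
  e <- seq(E - 1, E, by = 0.5)   # top bin at E keeps 300 keV inside the grid
  n <- ifelse(abs(e - E) < 1e-9, counts, 0)
  xray_spectrum(e, n, voltage = voltage, label = sprintf("mono_%g", E))
}

# spectrum with lines at the given energies (zeros elsewhere on the grid)
line_spectrum <- function(energies, counts, voltage = NA_real_) {
  e <- seq(min(energies), max(energies), by = 0.5)
  n <- numeric(length(e))
  for (i in seq_along(energies))
    n[which.min(abs(e - energies[i]))] <- counts[i]
  xray_spectrum(e, n, voltage = voltage,
                label = paste0("lines_", paste(energies, collapse = "_")))
}

# toy coefficient library usable wherever water (H, O) and aluminium are
# needed; pure power laws so closed forms hold exactly
toy_library <- function(muen_factor_H = 0.9, muen_factor_O = 0.8,
                        muen_factor_Al = 0.85) {
  structure(list(
    H = toy_coeff_table("H", 1L, 1.008, 8.4e-5, a = 5, p = 2.5,
                        muen_factor = muen_factor_H),
    O = toy_coeff_table("O", 8L, 15.999, 1.3e-3, a = 800, p = 2.8,
                        muen_factor = muen_factor_O),
    Al = toy_coeff_table("Al", 13L, 26.982, 2.699, a = 2000, p = 2.8,
                         muen_factor = muen_factor_Al)),
    class = "coeff_library")
}
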