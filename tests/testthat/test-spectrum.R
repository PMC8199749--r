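# Spectrum container, file I/O, beam-quality metrics, water attenuation.

test_that("spectrum constructor enforces its invariants", {
  expect_error(xray_spectrum(c(10, 10.6), c(1, 1)), "spaced")
  expect_error(xray_spectrum(c(10, 10.5), c(1, -1)), "non-negative")
  expect_error(xray_spectrum(c(10, 10.5, 11), c(1, 1, 1), voltage = 10.7),
               "exceed")
  s <- xray_spectrum(c(10, 10.5, 11), c(1, 0, 2), voltage = 11)
  expect_s3_class(s, "xray_spectrum")
})

test_that("write/read round trip preserves counts and metadata exactly", {
  set.seed(31)
  e <- seq(5, 70, by = 0.5)
  s <- xray_spectrum(e, runif(length(e)), voltage = 70, anode = "W",
                     filters = "1.2 mm Al", label = "roundtrip")
  path <- tempfile(fileext = ".txt")
  write_spectrum(s, path)
  r <- read_spectrum(path)
  expect_identical(r$counts, s$counts)
  expect_identical(r$energy, s$energy)
  expect_equal(r$voltage, 70)
  expect_identical(r$anode, "W")
  expect_identical(r$label, s$label)
  # a generated spectrum round-trips up to the documented read-time
  # truncation of counts below 1e-12 of the maximum
  g <- tube_spectrum(70, "W", filter_stack(Al = 1.2), tables = TABS)
  write_spectrum(g, path)
  r2 <- read_spectrum(path)
  kept <- g$counts >= 1e-12 * max(g$counts)
  expect_identical(r2$counts[kept], g$counts[kept])
  expect_true(all(r2$counts[!kept] == 0))
})

test_that("reader rejects bad files and rebins 1 keV grids with a warning", {
  p <- tempfile()
  writeLines(c("# label: bad", "10 5", "10.5 -2"), p)
  expect_error(read_spectrum(p), "negative")
  writeLines(c("10 1", "10.5 1", "11.5 1"), p)
  expect_error(read_spectrum(p), "non-uniform")
  writeLines(c("# label: coarse", "10 4", "11 2", "12 6"), p)
  expect_warning(r <- read_spectrum(p), "rebinning")
  expect_equal(sum(r$counts), 12)              # counts conserved
  expect_equal(diff(r$energy), rep(0.5, 5), tolerance = 1e-12)
})

test_that("average energy is the fluence-weighted mean", {
  expect_equal(average_energy(mono_spectrum(60)), 60)
  expect_equal(average_energy(line_spectrum(c(40, 80), c(1, 1))), 60)
  expect_equal(average_energy(line_spectrum(c(20, 40), c(1, 3))), 35)
  expect_error(average_energy(xray_spectrum(c(10, 10.5), c(0, 0))),
               "no counts")
})

test_that("monochromatic HVL matches the closed form ln2/mu_Al(E)", {
  for (E in c(10, 17, 30, 55, 120, 300)) {
    closed <- 10 * log(2) /
      (coeff_at(TABS$Al, E, "total_attenuation") * 2.699)
    expect_equal(hvl_al(mono_spectrum(E), TABS), closed,
                 tolerance = 1e-5, label = sprintf("E=%g", E))
  }
})

test_that("two-line HVL matches a brute-force solve of the half-fluence
           equation", {
  s <- line_spectrum(c(30, 80), c(1 / 30, 1 / 80))  # equal energy fluence
  w <- s$counts * s$energy
  mu <- coeff_at(TABS$Al, s$energy, "total_attenuation") * 2.699
  lhs <- function(t_mm) sum(w * exp(-mu * t_mm / 10))
  brute <- uniroot(function(t) lhs(t) - 0.5 * sum(w), c(0, 100),
                   tol = 1e-12)$root
  expect_equal(hvl_al(s, TABS), brute, tolerance = 1e-9)
  # coarse scan agrees to its own resolution
  grid <- seq(0, 20, by = 1e-4)
  scan <- grid[which.max(vapply(grid, lhs, 1) <= 0.5 * sum(w))]
  expect_lt(abs(hvl_al(s, TABS) - scan), 2e-4)
})

test_that("added filtration strictly increases HVL and effective energy", {
  s0 <- tube_spectrum(100, tables = TABS)
  s1 <- apply_filters(s0, filter_stack(Cu = 0.3), TABS)
  expect_gt(hvl_al(s1, TABS), hvl_al(s0, TABS))
  expect_gt(effective_energy(s1, TABS), effective_energy(s0, TABS))
})

test_that("effective energy is self-consistent on monochromatic beams", {
  for (E in c(15, 50, 140, 280))
    expect_equal(effective_energy(mono_spectrum(E), TABS), E,
                 tolerance = 1e-4, label = sprintf("E=%g", E))
})

test_that("two-line effective energy equals the inverted brute-force HVL", {
  s <- line_spectrum(c(30, 80), c(1 / 30, 1 / 80))
  w <- s$counts * s$energy
  mu <- coeff_at(TABS$Al, s$energy, "total_attenuation") * 2.699
  brute_hvl <- uniroot(function(t) sum(w * exp(-mu * t / 10)) - 0.5 * sum(w),
                       c(0, 100), tol = 1e-12)$root
  brute_E <- uniroot(function(E)
    10 * log(2) / (coeff_at(TABS$Al, E, "total_attenuation") * 2.699) -
      brute_hvl, c(2, 300), tol = 1e-9)$root
  expect_equal(effective_energy(s, TABS), brute_E, tolerance = 1e-6)
})

test_that("water attenuation: identity, halving depth, bin-wise factors", {
  s <- tube_spectrum(80, tables = TABS)
  expect_identical(attenuate(s, 0, tables = TABS), s)
  k <- mixture_coeff(WATER_COMPOSITION, 20, "energy_absorption", TABS)
  m <- mono_spectrum(20)
  att <- attenuate(m, log(2) / k, tables = TABS)  # one half-value depth
  expect_equal(att$counts[att$energy == 20], 0.5, tolerance = 1e-12)
  # two bins, 2 cm: exact hand factors; low-energy bin suppressed more
  tb <- line_spectrum(c(20, 100), c(1, 1))
  a2 <- attenuate(tb, 2, tables = TABS)
  for (E in c(20, 100)) {
    kE <- mixture_coeff(WATER_COMPOSITION, E, "energy_absorption", TABS)
    expect_equal(a2$counts[a2$energy == E], exp(-kE * 2), tolerance = 1e-12)
  }
  expect_lt(a2$counts[a2$energy == 20], a2$counts[a2$energy == 100])
  expect_error(attenuate(s, -1, tables = TABS), "non-negative")
  expect_warning(attenuate(s, 6, tables = TABS), "5 cm")
})

test_that("attenuation composes additively in depth", {
  s <- tube_spectrum(150, "W", filter_stack(Al = 2), tables = TABS)
  once <- attenuate(s, 3.7, tables = TABS)
  twice <- attenuate(attenuate(s, 1.2, tables = TABS), 2.5, tables = TABS)
  expect_equal(twice$counts, once$counts, tolerance = 1e-12)
})

test_that("attenuation hardens every generated test beam", {
  lib <- generate_library(library_config(n_spectra = 12, seed = 5),
                          tables = TABS)
  for (s in lib) {
    e0 <- effective_energy(s, TABS)
    # true (total-attenuation) transport always hardens
    e1 <- effective_energy(attenuate(s, 1, mode = "total_attenuation",
                                     tables = TABS), TABS)
    expect_gte(e1, e0 - 1e-9)
    # the energy-absorption depth rule hardens beams in the kilovoltage
    # working range (it can soften ultra-hard beams marginally, because the
    # water energy-absorption coefficient rises above ~100 keV)
    if (e0 < 80) {
      e2 <- effective_energy(attenuate(s, 1, tables = TABS), TABS)
      expect_gte(e2, e0 - 1e-9)
    }
  }
})
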