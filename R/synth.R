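# Parametric kilovoltage tube-spectrum generator: Kramers continuum,
# characteristic anode lines, Beer-Lambert filtration, library sampling.

#' Filter materials available to the spectrum generator
#' @export
FILTER_MATERIALS <- c("Al", "Cu", "Pd", "Mo", "Rh", "Ba", "Sb", "V", "Mn",
                      "Fe", "Ni", "Zr", "Sn", "Pb", "H2O")

# log-uniform thickness sampling ranges (mm) for random filter stacks
FILTER_THICKNESS_RANGES <- list(
  Al = c(0.5, 5), Cu = c(0.05, 3), Sn = c(0.1, 5), Pb = c(0.1, 5))
FILTER_THICKNESS_DEFAULT <- c(0.05, 1)

# Characteristic emission lines (keV) with nominal relative intensities and
# the excitation edge that must be exceeded by the tube voltage.
CHARACTERISTIC_LINES <- list(
  W = list(
    list(edge = 69.5, energies = c(57.98, 59.32, 67.24),
         weights = c(58, 100, 36)),                       # K series
    list(edge = 12.1, energies = c(8.40, 9.67, 11.29),
         weights = c(100, 80, 20))),                      # L series
  Mo = list(list(edge = 20.0, energies = c(17.48, 19.61),
                 weights = c(100, 20))),
  Rh = list(list(edge = 23.2, energies = c(20.22, 22.72),
                 weights = c(100, 20))))

ANODE_Z <- c(W = 74L, Mo = 42L, Rh = 45L)

#' Unfiltered Kramers continuum
#'
#' Thin-target bremsstrahlung model: photon counts per bin proportional to
#' \eqn{Z (U - E)/E} on the 0.5 keV grid from 1 keV to the tube voltage U,
#' normalised to `total_counts`. The count at E = U is zero.
#'
#' @param voltage tube voltage U, kVp, in [30, 300].
#' @param anode_Z anode atomic number (scales the overall intensity).
#' @param total_counts normalisation of the summed counts.
#' @return An [xray_spectrum] (label and metadata filled in).
#' @export
kramers_continuum <- function(voltage, anode_Z = 74L, total_counts = 1e6) {
  if (!is.numeric(voltage) || length(voltage) != 1L ||
      voltage < 30 || voltage > 300)
    stop("voltage must lie in [30, 300] kVp")
  e <- seq(1, voltage, by = BIN_WIDTH_KEV)
  n <- anode_Z * (voltage - e) / e
  if (total_counts > 0 && sum(n) > 0) n <- n * total_counts / sum(n)
  anode <- names(ANODE_Z)[match(anode_Z, ANODE_Z)]
  xray_spectrum(e, n, voltage = voltage,
                anode = ifelse(is.na(anode), NA_character_, anode),
                label = sprintf("kramers_%gkVp_Z%d", voltage, anode_Z))
}

#' Superpose characteristic anode lines on a continuum
#'
#' Adds the anode's K and L emission lines into the nearest bins, but only
#' for series whose excitation edge lies below the tube voltage. The total
#' added counts per series are `line_fraction` times the continuum counts
#' above that series' edge, split across the lines by nominal relative
#' intensities.
#'
#' @param spectrum continuum [xray_spectrum].
#' @param anode one of `"W"`, `"Mo"`, `"Rh"`.
#' @param voltage tube voltage, kVp; defaults to the spectrum metadata.
#' @param line_fraction line content as a fraction of the above-edge
#'   continuum counts (default 0.10); 0 returns the spectrum unchanged.
#' @return An [xray_spectrum].
#' @export
add_characteristic_lines <- function(spectrum, anode,
                                     voltage = spectrum$voltage,
                                     line_fraction = 0.10) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  if (!anode %in% names(CHARACTERISTIC_LINES))
    stop("unknown anode '", anode, "' (supported: ",
         paste(names(CHARACTERISTIC_LINES), collapse = ", "), ")")
  if (line_fraction == 0) return(spectrum)
  out <- spectrum
  for (series in CHARACTERISTIC_LINES[[anode]]) {
    if (is.na(voltage) || voltage <= series$edge) next
    budget <- line_fraction * sum(spectrum$counts[spectrum$energy > series$edge])
    keep <- series$energies <= max(spectrum$energy)
    if (budget <= 0 || !any(keep)) next
    w <- series$weights[keep] / sum(series$weights[keep])
    idx <- vapply(series$energies[keep],
                  function(E) which.min(abs(out$energy - E)), integer(1))
    for (j in seq_along(idx))
      out$counts[idx[j]] <- out$counts[idx[j]] + budget * w[j]
  }
  out$anode <- anode
  out
}

#' Build a filter stack
#'
#' Convenience constructor: `filter_stack(Be = 2, Al = 1.5, Cu = 0.25)`
#' gives an ordered data frame of (material, thickness_mm) layers. Materials
#' are element symbols or `"H2O"`.
#'
#' @param ... named thicknesses in mm.
#' @return Data frame with columns `material`, `thickness_mm`.
#' @export
filter_stack <- function(...) {
  t <- c(...)
  if (length(t) && (is.null(names(t)) || any(names(t) == "")))
    stop("filter_stack layers must be named, e.g. filter_stack(Al = 2)")
  if (any(t < 0)) stop("filter thicknesses must be >= 0")
  data.frame(material = names(t) %||% character(0),
             thickness_mm = as.numeric(t), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

filter_density <- function(material, tables) {
  if (material == "H2O") return(RHO_WATER)
  tab <- tables[[material]]
  if (is.null(tab)) stop("no coefficient table for filter material '",
                         material, "'")
  if (is.na(tab$density)) stop("no density recorded for filter material '",
                               material, "'")
  tab$density
}

filter_mu_rho <- function(material, energy, tables) {
  if (material == "H2O")
    return(mixture_coeff(WATER_COMPOSITION, energy, "total_attenuation",
                         tables))
  coeff_at(tables[[material]], energy, "total_attenuation")
}

#' Apply Beer-Lambert filtration
#'
#' Attenuates each bin by
#' \eqn{\prod_{layers} \exp(-(\mu/\rho)(E_i)\,\rho\,t)} using total
#' attenuation coefficients (coherent included). Layer order is immaterial.
#'
#' @param spectrum an [xray_spectrum].
#' @param stack a [filter_stack()] data frame (may be empty).
#' @param tables coefficient library.
#' @return Filtered [xray_spectrum], with the stack appended to the filter
#'   metadata.
#' @export
apply_filters <- function(spectrum, stack, tables = default_coefficients()) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  out <- spectrum
  if (!NROW(stack)) return(out)
  for (i in seq_len(nrow(stack))) {
    mat <- stack$material[i]; t_mm <- stack$thickness_mm[i]
    if (t_mm < 0) stop("negative filter thickness")
    if (t_mm == 0) next
    mu <- filter_mu_rho(mat, out$energy, tables) * filter_density(mat, tables)
    out$counts <- out$counts * exp(-mu * t_mm / 10)
  }
  desc <- paste(sprintf("%g mm %s", stack$thickness_mm, stack$material),
                collapse = " + ")
  out$filters <- if (nzchar(out$filters)) paste(out$filters, "+", desc) else desc
  out
}

#' Full synthetic tube spectrum
#'
#' Kramers continuum + characteristic lines + anode self-filtration +
#' beryllium window + external filter stack: the generator's standard
#' pipeline for one spectrum.
#'
#' @param voltage tube voltage, kVp.
#' @param anode `"W"`, `"Mo"` or `"Rh"`.
#' @param stack external [filter_stack()] (default none).
#' @param window_be_mm beryllium window thickness, mm (default 2).
#' @param anode_filter_mm fixed anode-material self-filtration, mm
#'   (default 0.005), a crude stand-in for target self-absorption.
#' @param line_fraction see [add_characteristic_lines()].
#' @param total_counts pre-filtration continuum normalisation.
#' @param label spectrum label.
#' @param tables coefficient library.
#' @return An [xray_spectrum].
#' @export
tube_spectrum <- function(voltage, anode = "W", stack = filter_stack(),
                          window_be_mm = 2, anode_filter_mm = 0.005,
                          line_fraction = 0.10, total_counts = 1e6,
                          label = NULL, tables = default_coefficients()) {
  s <- kramers_continuum(voltage, ANODE_Z[[anode]], total_counts)
  s <- add_characteristic_lines(s, anode, voltage, line_fraction)
  intrinsic <- filter_stack()
  if (anode_filter_mm > 0)
    intrinsic <- rbind(intrinsic, data.frame(material = anode,
                                             thickness_mm = anode_filter_mm))
  if (window_be_mm > 0)
    intrinsic <- rbind(intrinsic, data.frame(material = "Be",
                                             thickness_mm = window_be_mm))
  s <- apply_filters(s, intrinsic, tables)
  s <- apply_filters(s, stack, tables)
  s$label <- label %||% sprintf("%s_%gkVp", anode, voltage)
  s
}

#' Library sampling configuration
#'
#' @param n_spectra number of spectra to generate (default 237, the size of
#'   the study's spectrum set).
#' @param voltages tube voltages, kVp, each in [30, 300]; recycled across
#'   the library so the full range is covered (default 30-300 in 10 kVp
#'   steps).
#' @param anode_mix named proportions for the W/Mo/Rh anodes (default
#'   0.82/0.12/0.06); apportioned by largest remainder.
#' @param window_be_mm beryllium window, mm (default 2).
#' @param anode_filter_mm anode self-filtration, mm (default 0.005).
#' @param max_layers maximum number of random filter layers (0 to
#'   `max_layers` drawn uniformly).
#' @param line_fraction characteristic-line content.
#' @param total_counts pre-filtration counts per spectrum.
#' @param seed integer seed; the whole library is deterministic given it.
#' @return A `library_config` list.
#' @export
library_config <- function(n_spectra = 237, voltages = seq(30, 300, by = 10),
                           anode_mix = c(W = 0.82, Mo = 0.12, Rh = 0.06),
                           window_be_mm = 2, anode_filter_mm = 0.005,
                           max_layers = 3, line_fraction = 0.10,
                           total_counts = 1e6, seed = 1L) {
  if (any(voltages < 30 | voltages > 300))
    stop("voltages must lie in [30, 300] kVp")
  if (abs(sum(anode_mix) - 1) > 1e-9)
    stop("anode_mix proportions must sum to 1")
  if (!all(names(anode_mix) %in% names(ANODE_Z)))
    stop("anode_mix names must be among ", paste(names(ANODE_Z), collapse = ", "))
  structure(list(n_spectra = as.integer(n_spectra), voltages = voltages,
                 anode_mix = anode_mix, window_be_mm = window_be_mm,
                 anode_filter_mm = anode_filter_mm,
                 max_layers = as.integer(max_layers),
                 line_fraction = line_fraction, total_counts = total_counts,
                 seed = as.integer(seed)),
            class = "library_config")
}

# largest-remainder apportionment of n among proportions p
apportion <- function(n, p) {
  q <- n * p / sum(p)
  k <- floor(q)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(q - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  as.integer(k)
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sample_stack <- function(max_layers) {
  n_layers <- sample.int(max_layers + 1L, 1L) - 1L
  if (n_layers == 0L) return(filter_stack())
  mats <- sample(FILTER_MATERIALS, n_layers, replace = TRUE)
  th <- vapply(mats, function(m) {
    r <- FILTER_THICKNESS_RANGES[[m]] %||% FILTER_THICKNESS_DEFAULT
    exp(stats::runif(1, log(r[1]), log(r[2])))
  }, numeric(1))
  data.frame(material = mats, thickness_mm = as.numeric(th),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic spectrum library
#'
#' Draws `n_spectra` tube spectra emulating the statistical structure of a
#' kilovoltage spectrum set: voltages recycled over 30-300 kVp, anodes
#' apportioned to the configured W/Mo/Rh mix by largest remainder, and
#' 0-3 random filter layers per spectrum with log-uniform thicknesses over
#' clinical ranges. A sampled stack that transmits less than 1e-6 of the
#' unfiltered counts (a beam no tube set would contain) is redrawn. The
#' result is deterministic given the seed, and each spectrum carries its
#' provenance (voltage, anode, stack description, seed) in the metadata.
#'
#' @param config a [library_config()].
#' @param tables coefficient library.
#' @return List of [xray_spectrum] objects with attribute `manifest`
#'   (a data frame of per-spectrum metadata); class `spectrum_library`.
#' @export
generate_library <- function(config = library_config(),
                             tables = default_coefficients()) {
  stopifnot(inherits(config, "library_config"))
  n <- config$n_spectra
  counts <- apportion(n, config$anode_mix)
  with_local_seed(config$seed, {
    anodes <- sample(rep(names(config$anode_mix), counts))
    voltages <- rep_len(config$voltages, n)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      base <- tube_spectrum(voltages[i], anodes[i], filter_stack(),
                            config$window_be_mm, config$anode_filter_mm,
                            config$line_fraction, config$total_counts,
                            tables = tables)
      repeat {
        stack <- sample_stack(config$max_layers)
        s <- apply_filters(base, stack, tables)
        if (sum(s$counts) >= 1e-6 * sum(base$counts)) break
      }
      s$label <- sprintf("%s_%03d_%gkVp", anodes[i], i, voltages[i])
      out[[i]] <- s
    }
    manifest <- data.frame(
      label = vapply(out, `[[`, "", "label"),
      voltage = voltages, anode = anodes,
      filters = vapply(out, `[[`, "", "filters"),
      seed = config$seed, stringsAsFactors = FALSE)
    structure(out, manifest = manifest, class = "spectrum_library")
  })
}

#' @export
print.spectrum_library <- function(x, ...) {
  m <- attr(x, "manifest")
  cat(sprintf("<spectrum_library> %d spectra, %g-%g kVp (seed %d)\n",
              length(x), min(m$voltage), max(m$voltage), m$seed[1]))
  cat("  anodes:", paste(sprintf("%s=%d", names(table(m$anode)),
                                 as.integer(table(m$anode))), collapse = ", "),
      "\n")
  invisible(x)
}

#' Preset therapy beams for the tumour scenario
#'
#' Four clinically flavoured beams (W anode, 3 mm Be window) with the
#' filtrations used for the single-field tumour simulation: 120 kVp
#' (0.5 mm Al + 0.1 mm Cu), 180 kVp (1.5 mm Al + 0.15 mm Cu), 200 kVp
#' (1.0 mm Al + 0.5 mm Cu) and 300 kVp (1.5 mm Al + 0.25 mm Cu).
#'
#' @param tables coefficient library.
#' @return Named list of four [xray_spectrum] objects.
#' @export
preset_beams <- function(tables = default_coefficients()) {
  spec <- list(
    `120 kVp` = list(v = 120, st = filter_stack(Al = 0.5, Cu = 0.10)),
    `180 kVp` = list(v = 180, st = filter_stack(Al = 1.5, Cu = 0.15)),
    `200 kVp` = list(v = 200, st = filter_stack(Al = 1.0, Cu = 0.50)),
    `300 kVp` = list(v = 300, st = filter_stack(Al = 1.5, Cu = 0.25)))
  lapply(spec, function(p)
    tube_spectrum(p$v, "W", p$st, window_be_mm = 3,
                  label = sprintf("preset_%gkVp", p$v), tables = tables))
}
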