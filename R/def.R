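# Dose enhancement factors: monochromatic, spectrum-weighted, at depth, and
# survey summaries over (spectrum x material x depth) grids.

#' Monochromatic dose enhancement factor
#'
#' Under electronic equilibrium the dose ratio between nanoparticle-loaded
#' water and plain water at one photon energy is the ratio of their mass
#' energy-absorption coefficients:
#' \eqn{DEF(E) = (\mu_{en}/\rho)_{mix}(E) / (\mu_{en}/\rho)_{water}(E)}.
#'
#' @param loaded a [np_loaded_water()] object.
#' @param energy photon energies, keV (vectorised), within 1-300.
#' @param tables coefficient library.
#' @return DEF values (dimensionless; 1 at concentration 0).
#' @export
def_mono <- function(loaded, energy, tables = default_coefficients()) {
  stopifnot(inherits(loaded, "loaded_water"))
  mixture_coeff(loaded$material, energy, "energy_absorption", tables) /
    mixture_coeff(WATER_COMPOSITION, energy, "energy_absorption", tables)
}

#' Spectrum-weighted dose enhancement factor
#'
#' Discretised polychromatic dose ratio over the binned spectrum:
#' \eqn{DEF = \sum_i N_i E_i (\mu_{en}/\rho)_{mix}(E_i) /
#'            \sum_i N_i E_i (\mu_{en}/\rho)_{water}(E_i)}.
#'
#' @param loaded a [np_loaded_water()] object.
#' @param spectrum an [xray_spectrum] with at least one non-zero count.
#' @param tables coefficient library.
#' @return DEF (dimensionless).
#' @export
def_spectrum <- function(loaded, spectrum, tables = default_coefficients()) {
  stopifnot(inherits(loaded, "loaded_water"))
  usable_spectrum(spectrum)
  w <- spectrum$counts * spectrum$energy
  num <- sum(w * mixture_coeff(loaded$material, spectrum$energy,
                               "energy_absorption", tables))
  den <- sum(w * mixture_coeff(WATER_COMPOSITION, spectrum$energy,
                               "energy_absorption", tables))
  num / den
}

#' DEF at depth in the water phantom
#'
#' Attenuates the spectrum through `depth` cm of water (see [attenuate()])
#' and evaluates the spectrum-weighted DEF of the hardened beam. The record
#' keys the result to the INITIAL spectrum's effective and average energy,
#' so depth series can be read against the unattenuated beam-quality axes.
#'
#' @param loaded a [np_loaded_water()] object.
#' @param spectrum an [xray_spectrum].
#' @param depth water depth, cm (0-5; beyond 5 warns).
#' @param mode attenuation coefficient kind (see [attenuate()]).
#' @param tables coefficient library.
#' @return One-row data frame: `spectrum_label`, `material`, `depth`,
#'   `def`, `voltage`, `effective_energy`, `average_energy`.
#' @export
def_at_depth <- function(loaded, spectrum, depth,
                         mode = c("energy_absorption", "total_attenuation"),
                         tables = default_coefficients()) {
  mode <- match.arg(mode)
  d <- if (depth > 0) attenuate(spectrum, depth, mode, tables) else spectrum
  data.frame(
    spectrum_label = spectrum$label,
    material = loaded$nanoparticle$name,
    depth = depth,
    def = def_spectrum(loaded, d, tables),
    voltage = spectrum$voltage,
    effective_energy = effective_energy(spectrum, tables),
    average_energy = average_energy(spectrum),
    stringsAsFactors = FALSE)
}

#' DEF survey over a spectrum library, material set and depth list
#'
#' Evaluates the full cross-product (spectrum, material, depth) and returns
#' one record per combination in deterministic (spectrum, material, depth)
#' order. Beam-quality metrics are computed once per spectrum, and refer to
#' the initial (surface) spectrum at all depths.
#'
#' @param library list of [xray_spectrum] (e.g. from [generate_library()]).
#' @param materials list of [np_loaded_water()] objects.
#' @param depths water depths, cm.
#' @param mode attenuation kind for depths > 0 (see [attenuate()]).
#' @param tables coefficient library.
#' @return Data frame of class `def_survey`.
#' @export
def_survey <- function(library, materials, depths = 0,
                       mode = c("energy_absorption", "total_attenuation"),
                       tables = default_coefficients()) {
  mode <- match.arg(mode)
  if (!length(library) || !length(materials) || !length(depths))
    stop("library, materials and depths must all be non-empty")
  if (inherits(library, "xray_spectrum")) library <- list(library)
  if (inherits(materials, "loaded_water")) materials <- list(materials)
  water_att <- function(s, d)
    if (d == 0) s$counts else
      s$counts * exp(-mixture_coeff(WATER_COMPOSITION, s$energy, mode,
                                    tables) * RHO_WATER * d)
  rows <- vector("list", length(library))
  for (i in seq_along(library)) {
    s <- library[[i]]
    usable_spectrum(s)
    eeff <- effective_energy(s, tables)
    eavg <- average_energy(s)
    muen_w <- mixture_coeff(WATER_COMPOSITION, s$energy, "energy_absorption",
                            tables)
    muen_m <- lapply(materials, function(m)
      mixture_coeff(m$material, s$energy, "energy_absorption", tables))
    grid <- expand.grid(mi = seq_along(materials), di = seq_along(depths))
    grid <- grid[order(grid$mi, grid$di), ]
    defs <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      w <- water_att(s, depths[grid$di[g]]) * s$energy
      defs[g] <- sum(w * muen_m[[grid$mi[g]]]) / sum(w * muen_w)
    }
    rows[[i]] <- data.frame(
      spectrum_label = s$label,
      material = vapply(materials[grid$mi],
                        function(m) m$nanoparticle$name, ""),
      depth = depths[grid$di],
      def = defs,
      voltage = s$voltage,
      effective_energy = eeff,
      average_energy = eavg,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("def_survey", "data.frame")
  attr(out, "mode") <- mode
  out
}

#' @export
print.def_survey <- function(x, ...) {
  cat(sprintf("<def_survey> %d records: %d spectra x %d materials x %d depths\n",
              nrow(x), length(unique(x$spectrum_label)),
              length(unique(x$material)), length(unique(x$depth))))
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' @export
summary.def_survey <- function(object, ...) summarize_minavgmax(object)

#' @export
plot.def_survey <- function(x, material = unique(x$material)[1],
                            depth = unique(x$depth)[1], ...) {
  d <- x[x$material == material & x$depth == depth, ]
  graphics::plot(d$effective_energy, d$def, xlab = "Effective energy (keV)",
                 ylab = "DEF",
                 main = sprintf("%s, depth %g cm", material, depth),
                 pch = 19, col = grDevices::hcl.colors(
                   100, "viridis")[cut(d$voltage, 100, labels = FALSE)], ...)
  invisible(x)
}

#' Min / average / max DEF per material and depth
#'
#' @param survey a [def_survey] table.
#' @return Data frame: `material`, `depth`, `def_min`, `def_avg`, `def_max`
#'   (arithmetic mean over spectra).
#' @export
summarize_minavgmax <- function(survey) {
  if (!nrow(survey)) stop("empty survey table")
  agg <- function(f, nm) {
    a <- stats::aggregate(def ~ material + depth, data = survey, FUN = f)
    names(a)[3] <- nm
    a
  }
  out <- Reduce(function(a, b) merge(a, b, by = c("material", "depth")),
                list(agg(min, "def_min"), agg(mean, "def_avg"),
                     agg(max, "def_max")))
  out[order(out$material, out$depth), ]
}

DEF_CLASS_BREAKS <- c(-Inf, 1.2, 1.4, 1.6, 1.8, 2.0, 2.2, Inf)
DEF_CLASS_LABELS <- c("<1.2", "1.2-1.4", "1.4-1.6", "1.6-1.8", "1.8-2.0",
                      "2.0-2.2", ">=2.2")

#' Distribution of spectra over DEF classes
#'
#' Counts records per DEF class (left-closed, right-open intervals
#' `<1.2, [1.2,1.4), ..., [2.0,2.2), >=2.2`) for each material and depth.
#' Counts per (material, depth) group always total the number of spectra.
#'
#' @param survey a [def_survey] table.
#' @return Data frame: `material`, `depth`, one column per DEF class.
#' @export
bin_distribution <- function(survey) {
  if (!nrow(survey)) stop("empty survey table")
  cl <- cut(survey$def, DEF_CLASS_BREAKS, labels = DEF_CLASS_LABELS,
            right = FALSE)
  tab <- as.data.frame.matrix(table(
    paste(survey$material, survey$depth, sep = "\r"), cl))
  key <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  out <- cbind(data.frame(material = key[, 1],
                          depth = as.numeric(key[, 2]),
                          stringsAsFactors = FALSE), tab)
  rownames(out) <- NULL
  out[order(out$material, out$depth), ]
}

#' Pairwise material dominance
#'
#' For each ordered material pair and depth, the percentage of spectra on
#' which the first ("row") material's DEF strictly exceeds the second's.
#' Ties count to neither side, so dominance(A,B) + dominance(B,A) <= 100,
#' with equality exactly when there are no ties.
#'
#' @param survey a [def_survey] table; all materials must have been
#'   evaluated on the identical spectrum set.
#' @return Data frame: `material_row`, `material_col`, `depth`,
#'   `dominance_pct`.
#' @export
pairwise_dominance <- function(survey) {
  mats <- unique(survey$material)
  depths <- unique(survey$depth)
  labs <- unique(survey$spectrum_label)
  get <- function(m, d) {
    sub <- survey[survey$material == m & survey$depth == d, ]
    if (nrow(sub) != length(labs) ||
        !setequal(sub$spectrum_label, labs))
      stop("materials were not evaluated on identical spectrum sets")
    sub$def[match(labs, sub$spectrum_label)]
  }
  rows <- list()
  for (d in depths) {
    defs <- lapply(mats, get, d = d)
    names(defs) <- mats
    for (a in mats) for (b in mats)
      rows[[length(rows) + 1L]] <- data.frame(
        material_row = a, material_col = b, depth = d,
        dominance_pct = if (a == b) 0 else
          100 * mean(defs[[a]] > defs[[b]]),
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dominance range across depths
#'
#' Formats [pairwise_dominance()] output as a matrix of `min-max%` strings
#' over the surveyed depths (a single number when the effect does not change
#' with depth).
#'
#' @param dominance output of [pairwise_dominance()].
#' @return Character matrix (row material x column material).
#' @export
dominance_range <- function(dominance) {
  mats <- unique(dominance$material_row)
  out <- matrix("", length(mats), length(mats),
                dimnames = list(mats, mats))
  for (a in mats) for (b in mats) {
    v <- dominance$dominance_pct[dominance$material_row == a &
                                   dominance$material_col == b]
    r <- range(round(v))
    out[a, b] <- if (r[1] == r[2]) sprintf("%d%%", r[1]) else
      sprintf("%d-%d%%", r[1], r[2])
  }
  out
}

#' High-DEF region in (voltage, effective energy) coordinates
#'
#' Selects the survey cells with DEF at or above a threshold and reports
#' their axis-aligned bounding ranges, locating the beam-quality region in
#' which a material performs best (the default threshold 2.3 outlines the
#' most beneficial region for gold at 10 mg/mL).
#'
#' @param survey a [def_survey] table, typically filtered to one material
#'   and depth.
#' @param threshold DEF threshold (> 1).
#' @return List with `cells` (the qualifying records), `voltage_range` and
#'   `effective_energy_range` (NA ranges when the selection is empty), and
#'   `threshold`.
#' @export
high_def_region <- function(survey, threshold = 2.3) {
  if (threshold <= 1) stop("threshold must exceed 1")
  cells <- survey[survey$def >= threshold, , drop = FALSE]
  rng <- function(v) if (nrow(cells)) range(v) else c(NA_real_, NA_real_)
  list(cells = as.data.frame(cells),
       voltage_range = rng(cells$voltage),
       effective_energy_range = rng(cells$effective_energy),
       threshold = threshold)
}
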