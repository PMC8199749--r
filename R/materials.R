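# Materials: compositions, electron fractions, Mayneord effective atomic
# number, nanoparticle-loaded water.

# Standard atomic weights (IUPAC, g/mol) and atomic numbers for the elements
# used by the study.
ATOMIC_DATA <- data.frame(
  symbol = c("H", "O", "Be", "Al", "V", "Mn", "Fe", "Ni", "Cu", "Zr", "Mo",
             "Rh", "Pd", "Ag", "Sn", "Sb", "Ba", "Ce", "Gd", "Tm", "Hf",
             "Ta", "W", "Pt", "Au", "Pb", "Bi"),
  Z = c(1L, 8L, 4L, 13L, 23L, 25L, 26L, 28L, 29L, 40L, 42L, 45L, 46L, 47L,
        50L, 51L, 56L, 58L, 64L, 69L, 72L, 73L, 74L, 78L, 79L, 82L, 83L),
  mass = c(1.008, 15.999, 9.0122, 26.982, 50.942, 54.938, 55.845, 58.693,
           63.546, 91.224, 95.95, 102.906, 106.42, 107.868, 118.71, 121.76,
           137.327, 140.116, 157.25, 168.934, 178.486, 180.948, 183.84,
           195.084, 196.967, 207.2, 208.980),
  stringsAsFactors = FALSE)

atomic_entry <- function(symbol) {
  i <- match(symbol, ATOMIC_DATA$symbol)
  if (anyNA(i))
    stop("no atomic data for element(s): ",
         paste(symbol[is.na(i)], collapse = ", "))
  ATOMIC_DATA[i, , drop = FALSE]
}

#' Dosimetric water composition
#'
#' Mass fractions \{H: 0.1119, O: 0.8881\}, the standard dosimetric
#' convention.
#' @format Named numeric vector.
#' @export
WATER_COMPOSITION <- c(H = 0.1119, O = 0.8881)

#' Define a material from explicit mass fractions
#'
#' @param name material name.
#' @param composition named numeric vector of element mass fractions; must
#'   sum to 1 within 1e-9, with unique element symbols and each fraction in
#'   (0, 1].
#' @return Object of class `np_material`.
#' @export
material <- function(name, composition) {
  if (is.null(names(composition)) || any(names(composition) == ""))
    stop("composition must be a named vector of mass fractions")
  if (anyDuplicated(names(composition)))
    stop("duplicate element symbols in composition")
  if (any(composition <= 0) || any(composition > 1))
    stop("mass fractions must lie in (0, 1]")
  if (abs(sum(composition) - 1) > 1e-9)
    stop("mass fractions must sum to 1 (got ", format(sum(composition)), ")")
  structure(list(name = name, composition = composition),
            class = "np_material")
}

#' @export
print.np_material <- function(x, ...) {
  cat(sprintf("<material> %s\n", x$name))
  for (s in names(x$composition))
    cat(sprintf("  %-2s %8.4f%%\n", s, 100 * x$composition[[s]]))
  invisible(x)
}

#' Build a material from a chemical formula
#'
#' Parses formulas such as `"Bi2O3"` or `"Au"` (element symbols with
#' positive integer counts) and converts stoichiometry to mass fractions
#' using standard atomic weights.
#'
#' @param formula chemical formula string.
#' @param name material name; defaults to the formula itself.
#' @return Object of class `np_material`.
#' @examples
#' from_formula("ZrO2")$composition  # Zr 0.7403, O 0.2597
#' @export
from_formula <- function(formula, name = formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("malformed formula: '", formula, "'")
  syms <- sub("[0-9]*$", "", parts)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", parts),
                           sub("^[A-Za-z]+", "", parts), "1"))
  if (any(cnt < 1)) stop("malformed formula: '", formula, "'")
  # merge repeated symbols
  counts <- tapply(cnt, syms, sum)
  ad <- atomic_entry(names(counts))
  mass <- as.numeric(counts) * ad$mass
  material(name, stats::setNames(mass / sum(mass), names(counts)))
}

#' Relative electron fractions of a material
#'
#' For mass fractions \eqn{w_i}, atomic numbers \eqn{Z_i} and atomic masses
#' \eqn{A_i}, the electron fraction of element i is
#' \eqn{a_i = (w_i Z_i / A_i) / \sum_j (w_j Z_j / A_j)}.
#'
#' @param mat a [material].
#' @return Named numeric vector of electron fractions (sums to 1).
#' @export
electron_fractions <- function(mat) {
  w <- as_composition(mat)
  ad <- atomic_entry(names(w))
  q <- w * ad$Z / ad$mass
  q / sum(q)
}

#' Mayneord effective atomic number
#'
#' Electron-fraction-weighted power mean
#' \eqn{Z_{eff} = (\sum_i a_i Z_i^{2.94})^{1/2.94}}. Always lies between the
#' smallest and largest constituent Z.
#'
#' @param mat a [material].
#' @return Effective atomic number (dimensionless).
#' @export
z_eff_mayneord <- function(mat) {
  a <- electron_fractions(mat)
  Z <- atomic_entry(names(a))$Z
  sum(a * Z^2.94)^(1 / 2.94)
}

#' Nanoparticle-loaded water
#'
#' Adds `concentration` mg of nanoparticle material per mL of water
#' (1000 mg water per mL), so the nanoparticle mass fraction is
#' \eqn{w_{NP} = c / (c + 1000)}. The resolved elemental composition
#' distributes \eqn{w_{NP}} over the nanoparticle's elements and
#' \eqn{1 - w_{NP}} over water's; elements shared with water (oxygen in the
#' oxides) are merged.
#'
#' @param np nanoparticle [material] (or formula string).
#' @param concentration mg/mL, >= 0. Zero resolves to pure water.
#' @return Object of class `loaded_water` with fields `nanoparticle`,
#'   `concentration`, `np_mass_fraction` and `material` (the resolved
#'   elemental composition).
#' @export
np_loaded_water <- function(np, concentration = 10) {
  if (is.character(np)) np <- from_formula(np)
  stopifnot(inherits(np, "np_material"))
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration < 0)
    stop("concentration must be a single non-negative number (mg/mL)")
  w_np <- concentration / (concentration + 1000)
  comp <- c(WATER_COMPOSITION * (1 - w_np), np$composition * w_np)
  comp <- tapply(comp, names(comp), sum)
  comp <- stats::setNames(as.numeric(comp), names(comp))
  comp <- comp[comp > 0]     # concentration 0 resolves to pure water
  comp <- comp / sum(comp)   # remove last-digit rounding
  label <- sprintf("%s %g mg/mL in water", np$name, concentration)
  structure(list(nanoparticle = np, concentration = concentration,
                 np_mass_fraction = w_np,
                 material = material(label, comp)),
            class = "loaded_water")
}

#' @export
print.loaded_water <- function(x, ...) {
  cat(sprintf("<loaded_water> %s (w_NP = %.6f)\n", x$material$name,
              x$np_mass_fraction))
  invisible(x)
}

#' The eleven nanoparticle materials of the survey
#'
#' Cu, ZrO2, Ag, CeO2, Gd2O3, Tm2O3, HfO2, Ta2O5, Bi2O3, Pt and Au, read
#' from the material library file shipped with the package.
#'
#' @param path material library file (delimited text, columns `name` and
#'   `formula`); defaults to the shipped library.
#' @return Named list of [material] objects.
#' @export
np_material_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "np_materials.txt", package = "npdef",
                        mustWork = TRUE)
  dat <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(dat)),
                function(i) from_formula(dat$formula[i], dat$name[i]))
  stats::setNames(out, dat$name)
}
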