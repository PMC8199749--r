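# Photon interaction coefficient tables: storage, interpolation, mixtures.

#' Coefficient kinds
#'
#' Photon coefficient tables carry two quantities per energy: the total mass
#' attenuation coefficient \eqn{\mu/\rho} (coherent scattering included),
#' which governs beam attenuation, and the mass energy-absorption coefficient
#' \eqn{\mu_{en}/\rho}, which governs locally absorbed dose under electronic
#' equilibrium. All user-facing functions take a `kind` argument restricted
#' to these two values.
#'
#' @format Character vector of the two admissible kinds.
#' @export
COEFF_KINDS <- c("total_attenuation", "energy_absorption")

.kind_column <- function(kind) {
  kind <- match.arg(kind, COEFF_KINDS)
  if (kind == "total_attenuation") "mu_rho" else "muen_rho"
}

#' Construct a per-element coefficient table
#'
#' Builds the container used throughout the package for one element's photon
#' coefficients on an energy grid. Absorption edges are represented by a
#' duplicated energy row (below-edge value first, above-edge value second);
#' at most one duplicate per edge is allowed.
#'
#' @param element element symbol, e.g. `"Au"`.
#' @param Z atomic number.
#' @param atomic_mass atomic mass, g/mol.
#' @param energies energy grid, keV, non-decreasing, spanning at least
#'   1--300 keV for library tables (not enforced here so that toy tables can
#'   be built for tests).
#' @param mu_rho total mass attenuation coefficient, cm^2/g, one per energy.
#' @param muen_rho mass energy-absorption coefficient, cm^2/g, one per energy.
#' @param density bulk density, g/cm^3 (used for filter and absorber
#'   thickness conversions); may be `NA`.
#' @return An object of class `coeff_table`.
#' @export
coeff_table <- function(element, Z, atomic_mass, energies, mu_rho, muen_rho,
                        density = NA_real_) {
  stopifnot(is.character(element), length(element) == 1L)
  energies <- as.numeric(energies)
  mu_rho <- as.numeric(mu_rho)
  muen_rho <- as.numeric(muen_rho)
  n <- length(energies)
  if (length(mu_rho) != n || length(muen_rho) != n || n < 2L)
    stop("coefficient table for ", element,
         ": energies and coefficient columns must have equal length >= 2")
  d <- diff(energies)
  if (any(d < 0))
    stop("coefficient table for ", element, ": energy grid is not monotone")
  # duplicated rows mark absorption edges; at most one duplicate per value
  dup <- energies[which(d == 0)]
  if (anyDuplicated(dup))
    stop("coefficient table for ", element,
         ": more than one duplicate row at an edge energy")
  if (any(mu_rho <= 0) || any(muen_rho <= 0))
    stop("coefficient table for ", element, ": non-positive coefficient")
  if (any(muen_rho > mu_rho * (1 + 1e-9)))
    stop("coefficient table for ", element,
         ": muen/rho exceeds mu/rho on the grid")
  structure(
    list(element = element, Z = as.integer(Z), atomic_mass = atomic_mass,
         density = density, energies = energies, mu_rho = mu_rho,
         muen_rho = muen_rho),
    class = "coeff_table")
}

#' @export
print.coeff_table <- function(x, ...) {
  cat(sprintf("<coeff_table> %s (Z=%d, A=%.4g g/mol, rho=%.4g g/cm^3)\n",
              x$element, x$Z, x$atomic_mass, x$density))
  cat(sprintf("  %d grid points, %.4g-%.4g keV, %d edge row(s)\n",
              length(x$energies), min(x$energies), max(x$energies),
              sum(diff(x$energies) == 0)))
  invisible(x)
}

# Elements required by the study: water, window/anode/filter set and the
# eleven nanoparticle materials.
REQUIRED_ELEMENTS <- c("H", "O", "Be", "Al", "V", "Mn", "Fe", "Ni", "Cu",
                       "Zr", "Mo", "Rh", "Pd", "Ag", "Sn", "Sb", "Ba", "Ce",
                       "Gd", "Tm", "Hf", "Ta", "W", "Pt", "Au", "Pb", "Bi")

#' Load per-element coefficient tables from a fixture directory
#'
#' Reads one delimited-text table per element. Each file has `#`-prefixed
#' header lines (`# element:`, `# Z:`, `# atomic_mass:`, `# density:`) and
#' three data columns: energy (keV), mu/rho and muen/rho (cm^2/g). The
#' package ships a full set under `extdata/photon_coeffs`; tables span
#' 1--300 keV and carry duplicated rows at absorption edges.
#'
#' @param source_directory directory holding `<symbol>.txt` files; defaults
#'   to the tables shipped with the package.
#' @param elements element symbols to load. All must be present.
#' @return Named list of [coeff_table] objects, class `coeff_library`.
#' @export
load_coefficients <- function(source_directory = NULL,
                              elements = REQUIRED_ELEMENTS) {
  if (is.null(source_directory))
    source_directory <- system.file("extdata", "photon_coeffs",
                                    package = "npdef", mustWork = TRUE)
  if (!dir.exists(source_directory))
    stop("coefficient directory not found: ", source_directory)
  out <- lapply(elements, function(sym) {
    path <- file.path(source_directory, paste0(sym, ".txt"))
    if (!file.exists(path))
      stop("no coefficient table for element '", sym, "' in ",
           source_directory)
    read_coeff_file(path)
  })
  names(out) <- elements
  structure(out, class = "coeff_library")
}

read_coeff_file <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key, default = NA_character_) {
    m <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", m[1]))
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines)],
                           col.names = c("energy", "mu_rho", "muen_rho"))
  coeff_table(element = meta("element", basename(path)),
              Z = as.integer(meta("Z")),
              atomic_mass = as.numeric(meta("atomic_mass")),
              density = as.numeric(meta("density")),
              energies = dat$energy, mu_rho = dat$mu_rho,
              muen_rho = dat$muen_rho)
}

# Package-level cache of the shipped tables.
.npdef_cache <- new.env(parent = emptyenv())

#' Default coefficient library shipped with the package
#'
#' Loads (once per session) the full element set under
#' `extdata/photon_coeffs`.
#'
#' @return A `coeff_library` (named list of [coeff_table]).
#' @export
default_coefficients <- function() {
  if (is.null(.npdef_cache$tables))
    .npdef_cache$tables <- load_coefficients()
  .npdef_cache$tables
}

#' Interpolate a coefficient at arbitrary energies
#'
#' Log-log linear interpolation between grid points, the standard scheme for
#' photon coefficient tables (exact for power-law segments, hence exact at
#' grid points). At a duplicated edge energy the query resolves to the
#' higher-energy branch; queries outside the grid span are an error rather
#' than an extrapolation.
#'
#' @param table a [coeff_table].
#' @param energy energies, keV (vectorised).
#' @param kind one of `"total_attenuation"`, `"energy_absorption"`.
#' @return Coefficient values, cm^2/g.
#' @export
coeff_at <- function(table, energy, kind = COEFF_KINDS) {
  col <- .kind_column(kind)
  e <- table$energies
  v <- table[[col]]
  n <- length(e)
  if (any(energy < e[1] | energy > e[n]))
    stop(sprintf("energy outside the %s grid span [%.4g, %.4g] keV",
                 table$element, e[1], e[n]))
  # findInterval returns the last grid index with e[i] <= x, so a query at a
  # duplicated edge energy lands on the upper branch.
  i <- pmin(pmax(findInterval(energy, e), 1L), n - 1L)
  le1 <- log(e[i]); le2 <- log(e[i + 1L])
  t <- ifelse(le2 > le1, (log(energy) - le1) / (le2 - le1), 0)
  exp((1 - t) * log(v[i]) + t * log(v[i + 1L]))
}

#' Mixture-rule coefficient for a compound or mixture
#'
#' Mass-fraction weighted sum of elemental coefficients,
#' \eqn{(\mu/\rho)_{mix} = \sum_i w_i (\mu/\rho)_i}, the standard elemental
#' mixture rule for photon mass coefficients.
#'
#' @param composition named numeric vector of element mass fractions
#'   (names are element symbols), or a [material] object.
#' @param energy energies, keV (vectorised).
#' @param kind one of `"total_attenuation"`, `"energy_absorption"`.
#' @param tables a `coeff_library`; defaults to the shipped tables.
#' @return Coefficient values, cm^2/g.
#' @export
mixture_coeff <- function(composition, energy, kind = COEFF_KINDS,
                          tables = default_coefficients()) {
  w <- as_composition(composition)
  if (abs(sum(w) - 1) > 1e-9)
    stop("mass fractions must sum to 1 (got ", format(sum(w)), ")")
  missing <- setdiff(names(w), names(tables))
  if (length(missing))
    stop("no coefficient table loaded for element(s): ",
         paste(missing, collapse = ", "))
  out <- 0
  for (sym in names(w))
    out <- out + w[[sym]] * coeff_at(tables[[sym]], energy, kind)
  out
}

as_composition <- function(x) {
  if (inherits(x, "np_material")) return(x$composition)
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("composition must be a named numeric vector or a material object")
}

#' Toy power-law coefficient table
#'
#' Builds a small synthetic table whose coefficients follow exact power laws
#' (optionally with one artificial absorption edge). Because log-log linear
#' interpolation is exact on power laws, these tables give closed-form
#' expected values for interpolation, attenuation and half-value-layer tests.
#'
#' @param element label for the toy element.
#' @param Z,atomic_mass,density nominal identity values.
#' @param a,p `mu/rho = a * E^-p` (E in keV).
#' @param muen_factor `muen/rho = muen_factor * mu/rho` (must be in (0, 1]).
#' @param edge optional edge energy, keV; above it `mu/rho` is multiplied by
#'   `edge_jump`.
#' @param edge_jump multiplicative jump at the edge.
#' @param energies grid, keV.
#' @return A [coeff_table].
#' @export
toy_coeff_table <- function(element = "X", Z = 10L, atomic_mass = 20,
                            density = 1, a = 100, p = 3, muen_factor = 0.9,
                            edge = NULL, edge_jump = 5,
                            energies = c(1, 2, 5, 10, 20, 50, 100, 200, 300)) {
  stopifnot(muen_factor > 0, muen_factor <= 1)
  e <- sort(energies)
  if (!is.null(edge)) e <- sort(c(e[abs(e / edge - 1) > 1e-6], edge, edge))
  mu <- a * e^(-p)
  if (!is.null(edge)) {
    above <- e > edge | (e == edge & duplicated(e))
    mu[above] <- mu[above] * edge_jump
  }
  coeff_table(element, Z, atomic_mass, e, mu, muen_factor * mu,
              density = density)
}
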