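# Material definitions and coefficient-table lookups.

# Package-level cache for parsed coefficient tables.
.pd_cache <- new.env(parent = emptyenv())

#' Built-in material compositions
#'
#' Mass-fraction compositions and densities for the media used by the phantom
#' and the beam line: water, ICRU-style soft tissue, cortical bone, inflated
#' lung, dry air and tungsten (target, flattening filter and jaws).
#'
#' @return tibble with columns `material`, `density` (g/cm3) and a list column
#'   `composition` (named numeric mass fractions)
#' @export
pd_material_library <- function() {
  tibble::tibble(
    material = c("water", "soft_tissue", "bone", "lung", "air", "tungsten"),
    density = c(1.0, 1.04, 1.92, 0.296, 0.001205, 19.3),
    composition = list(
      c(H = 0.111898, O = 0.888102),
      c(
        H = 0.102, C = 0.143, N = 0.034, O = 0.708, Na = 0.002,
        P = 0.003, S = 0.003, Cl = 0.002, K = 0.003
      ),
      c(
        H = 0.034, C = 0.155, N = 0.042, O = 0.435, Na = 0.001,
        Mg = 0.002, P = 0.103, S = 0.003, Ca = 0.225
      ),
      c(
        H = 0.103, C = 0.105, N = 0.031, O = 0.749, Na = 0.002,
        P = 0.002, S = 0.003, Cl = 0.003, K = 0.002
      ),
      c(N = 0.755, O = 0.232, Ar = 0.013),
      c(W = 1.0)
    )
  )
}

#' Create a material
#'
#' @param name one of the built-in materials (see [pd_material_library()]), or
#'   an arbitrary label if `density` and `composition` are supplied
#' @param density mass density in g/cm3 (required for custom materials)
#' @param composition named numeric vector of element mass fractions summing
#'   to 1 (required for custom materials)
#' @return a `pd_material` object
#' @examples
#' material("water")
#' @export
material <- function(name, density = NULL, composition = NULL) {
  lib <- pd_material_library()
  if (is.null(density) || is.null(composition)) {
    i <- match(name, lib$material)
    if (is.na(i)) {
      stop("unknown material '", name, "'; supply density and composition")
    }
    density <- lib$density[i]
    composition <- lib$composition[[i]]
  }
  stopifnot(density > 0)
  if (abs(sum(composition) - 1) > 1e-6) {
    stop("mass fractions must sum to 1 (got ", sum(composition), ")")
  }
  structure(
    list(name = name, density = density, composition = composition),
    class = "pd_material"
  )
}

#' @export
print.pd_material <- function(x, ...) {
  cat("<pd_material>", x$name, "- density", x$density, "g/cm3\n")
  comp <- paste0(names(x$composition), ":", signif(x$composition, 4))
  cat(" ", paste(comp, collapse = " "), "\n")
  invisible(x)
}

# Load a coefficient table, preferring the bundled TSV and falling back to
# on-the-fly computation for custom compositions.
#' @noRd
.pd_coef_table <- function(mat) {
  key <- mat$name
  if (!is.null(.pd_cache[[key]])) {
    return(.pd_cache[[key]])
  }
  path <- system.file("extdata", "xs", paste0(key, ".tsv"), package = "peridose")
  tab <- if (nzchar(path) && file.exists(path)) {
    tibble::as_tibble(utils::read.delim(path, sep = "\t"))
  } else {
    compute_coefficient_table(mat$composition)
  }
  .pd_cache[[key]] <- tab
  tab
}

# Log-log interpolation with linear fallback where values are non-positive.
#' @noRd
.pd_interp <- function(x, y, xout) {
  if (any(y <= 0)) {
    pmax(0, stats::approx(x, y, xout = xout, rule = 2)$y)
  } else {
    exp(stats::approx(log(x), log(y), xout = log(xout), rule = 2)$y)
  }
}

#' Look up interaction coefficients for a material
#'
#' Interpolates (log-log in energy) the bundled per-process mass attenuation
#' coefficients and the mass energy-absorption coefficient.
#'
#' @param mat a [material()] object
#' @param energy_mev photon energies in MeV, between 0.01 (the photon
#'   transport cutoff) and 8 MeV
#' @return tibble with columns `energy_mev`, `pe`, `incoherent`, `pair`,
#'   `total`, `muen` (cm^2/g)
#' @export
get_coefficients <- function(mat, energy_mev) {
  stopifnot(inherits(mat, "pd_material"))
  if (any(energy_mev < 0.01 - 1e-12) || any(energy_mev > 8 + 1e-12)) {
    stop(
      "energy out of tabulated range [0.01, 8] MeV ",
      "(10 keV is the photon transport cutoff)"
    )
  }
  tab <- .pd_coef_table(mat)
  tibble::tibble(
    energy_mev = energy_mev,
    pe = .pd_interp(tab$energy_mev, tab$pe, energy_mev),
    incoherent = .pd_interp(tab$energy_mev, tab$incoherent, energy_mev),
    pair = .pd_interp(tab$energy_mev, tab$pair, energy_mev),
    muen = .pd_interp(tab$energy_mev, tab$muen, energy_mev)
  ) |>
    dplyr::mutate(total = .data$pe + .data$incoherent + .data$pair)
}

#' Mass energy-absorption coefficient ratio of two materials
#'
#' The ratio (muen/rho)_a / (muen/rho)_b at a given energy, as used by the
#' red-bone-marrow dose model (soft tissue over bone at the mean energy of
#' the treatment beam).
#'
#' @param mat_a,mat_b [material()] objects or built-in material names
#' @param energy_mev photon energy in MeV
#' @return dimensionless ratio (vectorized over energy)
#' @export
muen_ratio <- function(mat_a, mat_b, energy_mev) {
  if (is.character(mat_a)) mat_a <- material(mat_a)
  if (is.character(mat_b)) mat_b <- material(mat_b)
  get_coefficients(mat_a, energy_mev)$muen /
    get_coefficients(mat_b, energy_mev)$muen
}

# Internal: pack cross-section tables for the C++ engine. Returns a list of
# lists (one per material name, in the given order).
#' @noRd
.pd_xs_pack <- function(material_names) {
  lapply(material_names, function(nm) {
    mat <- material(nm)
    tab <- .pd_coef_table(mat)
    list(
      energy = tab$energy_mev,
      pe = tab$pe,
      incoherent = tab$incoherent,
      pair = tab$pair,
      muen = tab$muen,
      density = mat$density
    )
  })
}

#' Sample photon interactions in a material
#'
#' Samples the interacting process (photoelectric, incoherent, pair) in
#' proportion to the per-process attenuation coefficients, then the
#' post-collision state: Klein-Nishina kinematics for Compton scattering
#' (scattered energy and polar angle obeying the Compton relation exactly),
#' full local absorption for the photoelectric effect, and local deposition of
#' the pair kinetic energy with two 511 keV annihilation photons for pair
#' production (reported energy is one annihilation quantum).
#'
#' @param mat a [material()] object
#' @param energy_mev incident photon energy in MeV (scalar, >= 0.01)
#' @param n number of independent samples
#' @return tibble with columns `process` ("photoelectric", "incoherent",
#'   "pair"), `energy_out` (MeV), `cos_theta`, `deposited` (MeV)
#' @export
sample_interaction <- function(mat, energy_mev, n = 1) {
  stopifnot(inherits(mat, "pd_material"), length(energy_mev) == 1, energy_mev >= 0.01)
  xs <- .pd_xs_pack(mat$name)[[1]]
  m <- pd_cpp_sample_interaction(xs, energy_mev, as.integer(n))
  tibble::tibble(
    process = c("photoelectric", "incoherent", "pair")[m[, 1] + 1],
    energy_out = m[, 2],
    cos_theta = m[, 3],
    deposited = m[, 4]
  )
}
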