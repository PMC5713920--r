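# Two-step 6 MV linac beam model.
#
# Step 1 simulates the treatment head once: electrons hit a thin tungsten
# target, bremsstrahlung photons pass a conical flattening filter, and the
# transmitted fluence is scored on 13 concentric annular rings (0.2 cm wide)
# on a plane below the filter, in 0.25 MeV energy bins. Step 2 re-emits
# photons from a point source using the stored ring spectra, collimated by
# rectangular tungsten jaws, so treatment simulations never re-model the head.

PD_BEAM_PLANE_CM <- 2.6 / 0.15  # ring tally plane distance below the target
PD_BEAM_RINGS <- 13
PD_RING_WIDTH_CM <- 0.2
PD_EBIN_WIDTH_MEV <- 0.25
PD_EMAX_MEV <- 8
PD_FILTER_PLANE_CM <- 10
PD_JAW_THICKNESS_CM <- 7.8
PD_SAD_CM <- 100

#' @noRd
.pd_tungsten_mu <- function(energy_mev) {
  w <- material("tungsten")
  get_coefficients(w, energy_mev)$total * w$density  # 1/cm
}

# half-normal characteristic bremsstrahlung angle (rad) for photon energy E
#' @noRd
.pd_brems_sigma <- function(energy_mev) {
  0.511 / (0.511 + energy_mev)
}

#' Design the conical flattening filter
#'
#' Solves, radius by radius, for the tungsten thickness that flattens the
#' expected energy-fluence profile of the raw bremsstrahlung cone on the ring
#' tally plane: the attenuated fluence at every radius is brought down to the
#' unfiltered fluence at the cone edge (where the filter thickness is zero).
#'
#' @param n_radii number of radial design points across the cone
#' @return tibble with `radius_cm` (on the ring plane) and `thickness_cm`
#' @export
design_flattening_filter <- function(n_radii = 27) {
  zp <- PD_BEAM_PLANE_CM
  rmax <- PD_BEAM_RINGS * PD_RING_WIDTH_CM
  radii <- seq(rmax / n_radii / 2, rmax - rmax / n_radii / 2,
    length.out = n_radii
  )
  egrid <- seq(0.125, PD_EMAX_MEV - 0.125, by = 0.25)
  mu <- .pd_tungsten_mu(egrid)
  # expected unfiltered energy fluence per unit area at radius r:
  # spectrum weight x photon surface density from the half-normal angle model
  spec <- .pd_raw_spectrum(egrid)
  fluence0 <- function(r) {
    theta <- atan(r / zp)
    sig <- .pd_brems_sigma(egrid)
    dens <- exp(-theta^2 / (2 * sig^2)) / sig # half-normal angular density
    jac <- 1 / (2 * pi * r * zp * (1 + (r / zp)^2))
    sum(spec * egrid * dens * jac)
  }
  f_edge <- fluence0(rmax)
  thick <- vapply(radii, function(r) {
    theta <- atan(r / zp)
    sig <- .pd_brems_sigma(egrid)
    dens <- exp(-theta^2 / (2 * sig^2)) / sig
    jac <- 1 / (2 * pi * r * zp * (1 + (r / zp)^2))
    e_terms <- spec * egrid * dens * jac
    slant <- 1 / cos(theta)
    f <- function(t) sum(e_terms * exp(-mu * t * slant)) - f_edge
    if (f(0) <= 0) {
      return(0)
    }
    stats::uniroot(f, c(0, 20), tol = 1e-6)$root
  }, numeric(1))
  tibble::tibble(radius_cm = radii, thickness_cm = thick)
}

# raw bremsstrahlung spectrum shape (photons per energy bin per electron),
# thin-target Kramers form averaged over the electron energy distribution
#' @noRd
.pd_raw_spectrum <- function(egrid) {
  ee <- seq(3, 9, by = 0.1)
  we <- stats::dnorm(ee, 6, 1 / 2.355)
  we <- we / sum(we)
  sapply(egrid, function(E) {
    sum(we * ifelse(ee > E, (ee - E) / E, 0))
  })
}

#' Simulate the treatment head (step one)
#'
#' Monte Carlo of the photon side of the treatment head: electron energies are
#' normal (mean 6 MeV, 1 MeV full width at half maximum), bremsstrahlung
#' photon energies follow a thin-target (Ee-E)/E spectrum, emission angles a
#' half-normal with the characteristic angle 0.511/(0.511+E) rad, and each
#' photon is attenuated by the conical flattening filter before being scored
#' by ring and energy bin on the tally plane.
#'
#' @param n_electrons number of source electrons
#' @param seed integer seed; required so the head simulation is reproducible
#' @param filter filter design, as returned by [design_flattening_filter()]
#' @return a `pd_beam_spectra` object: tibble with `ring`, `r_lo`, `r_hi`,
#'   `bin`, `e_lo`, `e_hi`, `weight` (transmitted photon weight per source
#'   electron); attributes record the plane distance and bookkeeping totals
#' @export
simulate_head <- function(n_electrons = 2e6, seed,
                          filter = design_flattening_filter()) {
  if (missing(seed)) stop("simulate_head() requires an explicit seed")
  set.seed(seed)
  n <- as.integer(n_electrons)
  ee <- stats::rnorm(n, 6, 1 / 2.355)
  ee <- pmax(ee, 0.6)
  # photon energy: envelope 1/E on [0.01, ee], accept with (ee-E)/(ee-0.01)
  e <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    cand <- 0.01 * (ee[todo] / 0.01)^stats::runif(length(todo))
    keep <- stats::runif(length(todo)) < (ee[todo] - cand) / (ee[todo] - 0.01)
    e[todo[keep]] <- cand[keep]
    todo <- todo[!keep]
  }
  theta <- abs(stats::rnorm(n, 0, .pd_brems_sigma(e)))
  zp <- PD_BEAM_PLANE_CM
  r <- zp * tan(theta)
  rmax <- PD_BEAM_RINGS * PD_RING_WIDTH_CM
  inside <- r < rmax & theta < pi / 2
  tfun <- stats::approxfun(filter$radius_cm, filter$thickness_cm,
    rule = 2
  )
  mu <- .pd_tungsten_mu(pmin(e, PD_EMAX_MEV))
  w <- exp(-mu * tfun(r) / cos(theta))
  ring <- pmin(floor(r / PD_RING_WIDTH_CM), PD_BEAM_RINGS - 1) + 1
  bin <- pmin(floor(e / PD_EBIN_WIDTH_MEV), PD_EMAX_MEV / PD_EBIN_WIDTH_MEV - 1) + 1
  tab <- tibble::tibble(
    ring = ring[inside], bin = bin[inside], w = w[inside]
  ) |>
    dplyr::group_by(.data$ring, .data$bin) |>
    dplyr::summarise(weight = sum(.data$w) / n, .groups = "drop")
  grid <- tidyr::expand_grid(
    ring = seq_len(PD_BEAM_RINGS),
    bin = seq_len(PD_EMAX_MEV / PD_EBIN_WIDTH_MEV)
  )
  out <- grid |>
    dplyr::left_join(tab, by = c("ring", "bin")) |>
    dplyr::mutate(
      weight = dplyr::coalesce(.data$weight, 0),
      r_lo = (.data$ring - 1) * PD_RING_WIDTH_CM,
      r_hi = .data$ring * PD_RING_WIDTH_CM,
      e_lo = (.data$bin - 1) * PD_EBIN_WIDTH_MEV,
      e_hi = .data$bin * PD_EBIN_WIDTH_MEV
    ) |>
    dplyr::select(
      "ring", "r_lo", "r_hi", "bin", "e_lo", "e_hi", "weight"
    )
  structure(out,
    class = c("pd_beam_spectra", class(out)),
    plane_cm = zp,
    n_electrons = n,
    weight_emitted_cone = sum(w[inside]) / n,
    seed = seed
  )
}

#' @export
print.pd_beam_spectra <- function(x, ...) {
  cat(
    "<pd_beam_spectra>", PD_BEAM_RINGS, "rings x",
    PD_EMAX_MEV / PD_EBIN_WIDTH_MEV, "energy bins; total weight",
    signif(sum(x$weight), 4), "photons/electron; mean energy",
    signif(beam_mean_energy(x), 4), "MeV\n"
  )
  invisible(x)
}

#' Fluence-weighted mean energy of a beam spectra set
#'
#' @param spectra a `pd_beam_spectra` object
#' @param by_ring if `TRUE`, return a tibble of per-ring mean energies
#' @return mean photon energy in MeV (scalar, or tibble with `ring`,
#'   `mean_energy_mev`)
#' @export
beam_mean_energy <- function(spectra, by_ring = FALSE) {
  emid <- (spectra$e_lo + spectra$e_hi) / 2
  if (!by_ring) {
    return(sum(spectra$weight * emid) / sum(spectra$weight))
  }
  tibble::tibble(ring = spectra$ring, w = spectra$weight, e = emid) |>
    dplyr::group_by(.data$ring) |>
    dplyr::summarise(
      mean_energy_mev = sum(.data$w * .data$e) / sum(.data$w),
      weight = sum(.data$w),
      .groups = "drop"
    )
}

#' Write / read beam spectra as plain text
#'
#' @param spectra a `pd_beam_spectra` object
#' @param path file path of the tab-separated table
#' @return `read_beam_spectra` returns a `pd_beam_spectra`;
#'   `write_beam_spectra` returns `path` invisibly
#' @export
write_beam_spectra <- function(spectra, path) {
  df <- as.data.frame(spectra)
  df$weight <- signif(df$weight, 8)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_beam_spectra
#' @export
read_beam_spectra <- function(path) {
  out <- tibble::as_tibble(utils::read.delim(path, sep = "\t"))
  structure(out,
    class = c("pd_beam_spectra", class(out)),
    plane_cm = PD_BEAM_PLANE_CM
  )
}

#' Bundled default beam spectra
#'
#' The package ships the step-one head simulation result (2e6 electrons,
#' fixed seed) as a plain-text table; this loads and caches it.
#'
#' @return a `pd_beam_spectra` object
#' @export
beam_spectra <- function() {
  if (!is.null(.pd_cache[["beam_spectra"]])) {
    return(.pd_cache[["beam_spectra"]])
  }
  path <- system.file("extdata", "beam", "spectra.tsv", package = "peridose")
  sp <- if (nzchar(path) && file.exists(path)) {
    read_beam_spectra(path)
  } else {
    simulate_head(2e5, seed = 20130613)
  }
  .pd_cache[["beam_spectra"]] <- sp
  sp
}

#' Define a collimated treatment field
#'
#' A field is a point photon source with an orthonormal beam frame and a
#' rectangular aperture specified at the reference distance (100 cm). The
#' aperture may be asymmetric in the width direction, which is how the
#' posterior borders of a tangential pair are matched.
#'
#' @param source length-3 source position (cm)
#' @param target length-3 point the central axis passes through (cm)
#' @param width_limits length-2 aperture limits (cm at 100 cm) along the
#'   horizontal width direction
#' @param height_limits length-2 aperture limits along the remaining
#'   transverse direction
#' @param label field name
#' @return a `pd_field` object
#' @export
beam_field <- function(source, target, width_limits, height_limits,
                       label = "field") {
  d <- target - source
  d <- d / sqrt(sum(d^2))
  u <- c(d[2], -d[1], 0) # horizontal, perpendicular to the axis
  if (sum(u^2) < 1e-12) u <- c(1, 0, 0) # axis along z: any transverse works
  u <- u / sqrt(sum(u^2))
  v <- c(
    d[2] * u[3] - d[3] * u[2],
    d[3] * u[1] - d[1] * u[3],
    d[1] * u[2] - d[2] * u[1]
  )
  structure(
    list(
      source = source, axis = d, width_dir = u, height_dir = v,
      width_limits = sort(width_limits), height_limits = sort(height_limits),
      label = label
    ),
    class = "pd_field"
  )
}

#' @export
print.pd_field <- function(x, ...) {
  cat(
    "<pd_field>", x$label, "- source (", paste(round(x$source, 1), collapse = ", "),
    ") aperture", diff(x$width_limits), "x", diff(x$height_limits), "cm at 100 cm\n"
  )
  invisible(x)
}

#' Emit photons from a field (step two)
#'
#' Samples photons from the stored annular ring spectra as if re-emitted from
#' the point source: ring by fluence weight, energy uniform within the chosen
#' bin, direction uniform over the ring's footprint, azimuth uniform. Photons
#' whose projection at 100 cm falls outside the rectangular aperture are
#' transmitted through the closed tungsten jaws with the corresponding
#' exponential attenuation weight (collimator leakage).
#'
#' @param field a [beam_field()]
#' @param n number of photons
#' @param spectra a `pd_beam_spectra` (default: the bundled head simulation)
#' @return tibble with `x`, `y`, `z`, `ux`, `uy`, `uz`, `energy`, `weight`,
#'   `in_field` (logical)
#' @export
emit_beam <- function(field, n, spectra = beam_spectra()) {
  stopifnot(inherits(field, "pd_field"))
  n <- as.integer(n)
  p <- spectra$weight / sum(spectra$weight)
  pick <- sample.int(nrow(spectra), n, replace = TRUE, prob = p)
  e <- stats::runif(n, pmax(spectra$e_lo[pick], 0.01), spectra$e_hi[pick])
  zp <- PD_BEAM_PLANE_CM
  r <- sqrt(stats::runif(n, spectra$r_lo[pick]^2, spectra$r_hi[pick]^2))
  phi <- stats::runif(n, 0, 2 * pi)
  v1 <- r * cos(phi)
  v2 <- r * sin(phi)
  nrm <- sqrt(v1^2 + v2^2 + zp^2)
  v1 <- v1 / nrm
  v2 <- v2 / nrm
  v3 <- zp / nrm
  a1 <- PD_SAD_CM * v1 / v3
  a2 <- PD_SAD_CM * v2 / v3
  in_field <- a1 >= field$width_limits[1] & a1 <= field$width_limits[2] &
    a2 >= field$height_limits[1] & a2 <= field$height_limits[2]
  w <- rep(1, n)
  if (any(!in_field)) {
    mu <- .pd_tungsten_mu(e[!in_field])
    w[!in_field] <- exp(-mu * PD_JAW_THICKNESS_CM / v3[!in_field])
  }
  u <- field$width_dir
  vv <- field$height_dir
  d <- field$axis
  tibble::tibble(
    x = field$source[1], y = field$source[2], z = field$source[3],
    ux = v1 * u[1] + v2 * vv[1] + v3 * d[1],
    uy = v1 * u[2] + v2 * vv[2] + v3 * d[2],
    uz = v1 * u[3] + v2 * vv[3] + v3 * d[3],
    energy = e, weight = w, in_field = in_field
  )
}

#' Analytic in-field fluence profile of a field at 100 cm
#'
#' The expected (jaw-free) relative fluence at transverse positions on the
#' reference plane, from the ring footprint geometry; used to verify that the
#' geometric field edge lands within tolerance of the nominal aperture edge.
#'
#' @param field a [beam_field()]
#' @param positions width-direction positions (cm) at 100 cm
#' @param n number of sampled photons
#' @param spectra a `pd_beam_spectra`
#' @return tibble with `position`, `fluence` (relative, max 1)
#' @export
field_edge_profile <- function(field, positions, n = 2e5,
                               spectra = beam_spectra()) {
  ph <- emit_beam(field, n, spectra)
  a1 <- PD_SAD_CM * (ph$ux * field$width_dir[1] + ph$uy * field$width_dir[2] +
    ph$uz * field$width_dir[3]) /
    (ph$ux * field$axis[1] + ph$uy * field$axis[2] + ph$uz * field$axis[3])
  h <- graphics::hist(a1[ph$in_field],
    breaks = c(-Inf, positions, Inf), plot = FALSE
  )
  cnt <- h$counts[-c(1, length(h$counts))]
  tibble::tibble(
    position = (positions[-1] + positions[-length(positions)]) / 2,
    fluence = cnt / max(cnt)
  )
}
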