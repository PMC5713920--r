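# Water-tank verification geometry, depth-dose and profile curves, and the
# distance-to-agreement metric.

PD_BUILDUP_RANGE_CM <- 0.38 # effective secondary-electron buildup range

#' Default depth grid for percent-depth-dose calculations
#' @return depths in cm
#' @export
pd_default_depths <- function() {
  c(seq(0.2, 3, by = 0.2), seq(3.5, 10, by = 0.5), seq(11, 30, by = 1))
}

#' Build the water-tank verification phantom
#'
#' A 50 x 50 x 50 cm water volume whose entrance surface is the z = 0 plane
#' (the beam travels along +z), with embedded cylindrical tally cells:
#' for `tally = "pdd"`, coaxial cylinders of radius 1 cm and height 0.2 cm
#' centered on the beam axis at the requested depths; for `tally = "profile"`,
#' an array of disjoint cylinders (radius at most 0.5 cm, shrunk to half
#' the offset spacing when needed; length 1 cm, axes parallel to the beam)
#' at the requested lateral offsets at one depth.
#'
#' @param tally `"pdd"` or `"profile"`
#' @param depths tally depths in cm (for `"pdd"`)
#' @param depth single tally depth in cm (for `"profile"`)
#' @param offsets lateral (x) offsets in cm (for `"profile"`)
#' @return a `pd_geometry`; tally cells are labelled `tally_<i>` and carry
#'   the depth or offset in the geometry's `tally_position` attribute
#' @export
build_water_phantom <- function(tally = c("pdd", "profile"),
                                depths = pd_default_depths(),
                                depth = 10, offsets = seq(-12, 12, by = 1)) {
  tally <- match.arg(tally)
  gb <- .gb_new()
  if (tally == "pdd") {
    pos <- depths
    for (i in seq_along(depths)) {
      d <- depths[i]
      .gb_cell(gb, paste0("tally_", i),
        inside = list(
          .sq_ezcyl(0, 0, 1, 1), .sq_plane("z", d + 0.1)
        ),
        outside = list(.sq_plane("z", d - 0.1)),
        material = "water", volume = pi * 0.2, organ = "tally"
      )
    }
  } else {
    pos <- offsets
    # keep neighbouring cylinders disjoint whatever the offset spacing
    r <- min(0.5, min(diff(sort(offsets))) / 2)
    for (i in seq_along(offsets)) {
      .gb_cell(gb, paste0("tally_", i),
        inside = list(
          .sq_ezcyl(offsets[i], 0, r, r), .sq_plane("z", depth + 0.5)
        ),
        outside = list(.sq_plane("z", depth - 0.5)),
        material = "water", volume = pi * r^2, organ = "tally"
      )
    }
  }
  n_t <- length(pos)
  .gb_cell(gb, "water",
    inside = list(
      .sq_plane("x", 25), .sq_plane("y", 25), .sq_plane("z", 50)
    ),
    outside = list(
      .sq_plane("x", -25), .sq_plane("y", -25), .sq_plane("z", 0)
    ),
    material = "water",
    volume = 50^3 - sum(vapply(gb$cells[seq_len(n_t)], `[[`, numeric(1), "volume")),
    organ = "water", excludes = paste0("tally_", seq_len(n_t))
  )
  geom <- .gb_finalize(gb)
  attr(geom, "tally_position") <- pos
  attr(geom, "tally_kind") <- tally
  geom
}

# square field centered on the vertical axis, source 100 cm above the tank
#' @noRd
.pd_square_field <- function(field_size) {
  h <- field_size / 2
  beam_field(
    source = c(0, 0, -PD_SAD_CM), target = c(0, 0, 0),
    width_limits = c(-h, h), height_limits = c(-h, h),
    label = sprintf("square_%gx%g", field_size, field_size)
  )
}

# charged-particle-equilibrium buildup factor applied to collision kerma
#' @noRd
.pd_buildup <- function(depth_cm) {
  1 - exp(-pmax(depth_cm, 0) / PD_BUILDUP_RANGE_CM)
}

#' Compute a percent depth dose curve
#'
#' Runs the beam onto the water tank and converts the per-cell collision
#' kerma to relative dose. Because the engine transports photons only, an
#' analytic charged-particle-equilibrium buildup factor `1 - exp(-d/R)`
#' (R = 0.38 cm) multiplies the kerma so the shallow buildup region behaves
#' like a megavoltage depth-dose curve; beyond the buildup depth the factor
#' is 1 and the curve is pure simulated kerma.
#'
#' @param field_size square field side in cm (at 100 cm)
#' @param n_histories number of source photons
#' @param seed integer seed (required)
#' @param depths tally depths in cm
#' @param spectra beam spectra (default: bundled head simulation)
#' @return a `pd_pdd` tibble: `depth_cm`, `dose` (relative), `pdd` (percent
#'   of maximum), `rel_err`; attributes `dmax_cm` and `pdd10`
#' @export
compute_pdd <- function(field_size = 10, n_histories = 2e5, seed,
                        depths = pd_default_depths(),
                        spectra = beam_spectra()) {
  if (missing(seed)) stop("compute_pdd() requires an explicit seed")
  geom <- build_water_phantom("pdd", depths = depths)
  set.seed(seed)
  ph <- emit_beam(.pd_square_field(field_size), n_histories, spectra)
  tl <- run_transport(geom, ph, seed = seed + 1)
  i <- match(paste0("tally_", seq_along(depths)), tl$cell)
  dose <- tl$kerma_mev_g[i] * .pd_buildup(depths)
  out <- tibble::tibble(
    depth_cm = depths,
    dose = dose / max(dose),
    pdd = 100 * dose / max(dose),
    rel_err = tl$kerma_rel_err[i]
  )
  class(out) <- c("pd_pdd", class(out))
  attr(out, "dmax_cm") <- depths[which.max(dose)]
  attr(out, "pdd10") <- stats::approx(depths, out$pdd, xout = 10)$y
  attr(out, "field_size") <- field_size
  out
}

#' Compute a lateral dose profile
#'
#' @param field_size square field side in cm (at 100 cm)
#' @param depth profile depth in cm
#' @param n_histories number of source photons
#' @param seed integer seed (required)
#' @param offsets lateral offsets in cm
#' @param spectra beam spectra
#' @return a `pd_profile` tibble: `position_cm`, `dose` (relative to the
#'   central axis), `rel_err`; attribute `depth_cm`
#' @export
compute_profile <- function(field_size = 10, depth = 10, n_histories = 2e5,
                            seed, offsets = seq(-9, 9, by = 0.75),
                            spectra = beam_spectra()) {
  if (missing(seed)) stop("compute_profile() requires an explicit seed")
  geom <- build_water_phantom("profile", depth = depth, offsets = offsets)
  set.seed(seed)
  ph <- emit_beam(.pd_square_field(field_size), n_histories, spectra)
  tl <- run_transport(geom, ph, seed = seed + 1)
  i <- match(paste0("tally_", seq_along(offsets)), tl$cell)
  ctr <- stats::approx(offsets, tl$kerma_mev_g[i], xout = 0)$y
  out <- tibble::tibble(
    position_cm = offsets,
    dose = tl$kerma_mev_g[i] / ctr,
    rel_err = tl$kerma_rel_err[i]
  )
  class(out) <- c("pd_profile", class(out))
  attr(out, "depth_cm") <- depth
  attr(out, "field_size") <- field_size
  out
}

#' @rdname tidy_peridose
#' @export
glance.pd_pdd <- function(x, ...) {
  tibble::tibble(
    dmax_cm = attr(x, "dmax_cm"),
    pdd10 = attr(x, "pdd10"),
    field_size = attr(x, "field_size"),
    n_depths = nrow(x)
  )
}

#' @rdname tidy_peridose
#' @export
glance.pd_profile <- function(x, ...) {
  tibble::tibble(
    depth_cm = attr(x, "depth_cm"),
    field_size = attr(x, "field_size"),
    n_positions = nrow(x)
  )
}

#' Distance to agreement between a curve and a reference
#'
#' For each evaluation point, the shortest spatial distance to any location
#' where the (linearly interpolated) reference curve takes the same value.
#' Restricted by default to the high-gradient region where the value lies
#' between 20% and 80% of the reference maximum, which is where the metric
#' is meaningful.
#'
#' @param position,value evaluated curve (positions in cm, relative values)
#' @param ref_position,ref_value reference curve
#' @param region value range (fractions of the reference maximum) defining
#'   the evaluated points
#' @return tibble with `position`, `value`, `dta_cm`; attribute `max_dta_cm`
#' @export
dta <- function(position, value, ref_position, ref_value,
                region = c(0.2, 0.8)) {
  vmax <- max(ref_value)
  sel <- value >= region[1] * vmax & value <= region[2] * vmax
  crossings <- function(v) {
    x <- numeric(0)
    for (j in seq_len(length(ref_position) - 1)) {
      v0 <- ref_value[j]
      v1 <- ref_value[j + 1]
      if ((v0 - v) * (v1 - v) <= 0 && v0 != v1) {
        f <- (v - v0) / (v1 - v0)
        x <- c(x, ref_position[j] + f * (ref_position[j + 1] - ref_position[j]))
      } else if (v0 == v && v1 == v) {
        x <- c(x, ref_position[j], ref_position[j + 1])
      }
    }
    x
  }
  d <- vapply(which(sel), function(i) {
    x <- crossings(value[i])
    if (!length(x)) {
      return(NA_real_)
    }
    min(abs(x - position[i]))
  }, numeric(1))
  out <- tibble::tibble(
    position = position[sel], value = value[sel], dta_cm = d
  )
  attr(out, "max_dta_cm") <- if (all(is.na(d))) NA_real_ else max(d, na.rm = TRUE)
  out
}
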