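# Constructive-solid-geometry building blocks.
#
# A geometry is a list of quadric surfaces plus cells defined as intersections
# of half-spaces (signed surface references), optionally minus excluded cells.
# Cells carry a material, an organ label, and bookkeeping volume/mass.

# -- quadric surface constructors (coefficient rows) --------------------------
# Q(p) = A x^2 + B y^2 + C z^2 + D xy + E yz + F zx + G x + H y + I z + J

#' @noRd
.sq_plane <- function(axis, pos) {
  # Q = axis_coord - pos  (Q < 0 means below/behind the plane)
  v <- numeric(10)
  v[6 + match(axis, c("x", "y", "z"))] <- 1
  v[10] <- -pos
  v
}

#' @noRd
.sq_sphere <- function(center, r) {
  c(1, 1, 1, 0, 0, 0, -2 * center, sum(center^2) - r^2)
}

#' @noRd
.sq_ellipsoid <- function(center, semi) {
  a2 <- semi^2
  c(
    1 / a2[1], 1 / a2[2], 1 / a2[3], 0, 0, 0,
    -2 * center[1] / a2[1], -2 * center[2] / a2[2], -2 * center[3] / a2[3],
    sum(center^2 / a2) - 1
  )
}

# elliptical cylinder along z, cross-section semi-axes (a, b) at (cx, cy)
#' @noRd
.sq_ezcyl <- function(cx, cy, a, b) {
  c(
    1 / a^2, 1 / b^2, 0, 0, 0, 0,
    -2 * cx / a^2, -2 * cy / b^2, 0, cx^2 / a^2 + cy^2 / b^2 - 1
  )
}

# circular cone/frustum along z centered (cx, cy): radius r(z) = r0 + m*(z-z0)
#' @noRd
.sq_zcone <- function(cx, cy, r0, z0, m) {
  k <- r0 - m * z0
  c(
    1, 1, -m^2, 0, 0, 0,
    -2 * cx, -2 * cy, -2 * m * k, cx^2 + cy^2 - k^2
  )
}

# -- geometry builder ---------------------------------------------------------

#' @noRd
.gb_new <- function() {
  env <- new.env(parent = emptyenv())
  env$surfaces <- list()
  env$cells <- list()
  env
}

# register a surface (deduplicated), return its 1-based id
#' @noRd
.gb_surface <- function(gb, coefs) {
  key <- paste(signif(coefs, 12), collapse = ",")
  if (is.null(gb$surf_keys)) gb$surf_keys <- character(0)
  hit <- match(key, gb$surf_keys)
  if (!is.na(hit)) {
    return(hit)
  }
  gb$surfaces[[length(gb$surfaces) + 1]] <- coefs
  gb$surf_keys <- c(gb$surf_keys, key)
  length(gb$surfaces)
}

# add a cell; `inside`/`outside` are lists of surface coefficient rows;
# `excludes` are names of previously added cells
#' @noRd
.gb_cell <- function(gb, name, inside = list(), outside = list(),
                     material = "soft_tissue", volume = NA_real_,
                     organ = NA_character_, excludes = character(0)) {
  sids <- c(
    vapply(inside, function(s) .gb_surface(gb, s), numeric(1)),
    -vapply(outside, function(s) .gb_surface(gb, s), numeric(1))
  )
  gb$cells[[length(gb$cells) + 1]] <- list(
    name = name, surf = as.integer(sids), material = material,
    volume = volume, organ = organ, excludes = excludes
  )
  invisible(name)
}

#' @noRd
.gb_finalize <- function(gb, world_radius = 300) {
  # world cell: everything inside a bounding sphere not claimed by any cell
  names_all <- vapply(gb$cells, `[[`, character(1), "name")
  .gb_cell(gb, "world",
    inside = list(.sq_sphere(c(0, 0, 0), world_radius)),
    material = "air", volume = 4 / 3 * pi * world_radius^3,
    organ = "world", excludes = names_all
  )
  cells <- gb$cells
  nm <- vapply(cells, `[[`, character(1), "name")
  stopifnot(!anyDuplicated(nm))
  mats <- unique(vapply(cells, `[[`, character(1), "material"))
  dens <- vapply(mats, function(m) material(m)$density, numeric(1))
  vol <- vapply(cells, `[[`, numeric(1), "volume")
  mat_id <- match(vapply(cells, `[[`, character(1), "material"), mats)
  excl <- lapply(cells, function(cl) {
    idx <- match(cl$excludes, nm)
    if (anyNA(idx)) stop("unknown excluded cell(s) in ", cl$name)
    as.integer(idx)
  })
  # world volume: bounding sphere minus the claimed cells
  vol[length(vol)] <- vol[length(vol)] - sum(vol[-length(vol)])
  geom <- list(
    surfaces = do.call(rbind, gb$surfaces),
    cells = lapply(cells, `[[`, "surf"),
    exclusions = excl,
    label = nm,
    organ = vapply(cells, `[[`, character(1), "organ"),
    material = vapply(cells, `[[`, character(1), "material"),
    material_id = mat_id,
    materials = mats,
    volume = vol,
    mass = unname(vol * dens[mat_id])
  )
  class(geom) <- "pd_geometry"
  geom
}

#' @export
print.pd_geometry <- function(x, ...) {
  cat(
    "<pd_geometry>", length(x$cells), "cells,", nrow(x$surfaces),
    "surfaces, total mass",
    round(sum(x$mass[x$label != "world"]) / 1000, 2), "kg\n"
  )
  invisible(x)
}

#' Locate points in a geometry
#'
#' Deterministic point membership: the first cell (in fixed cell order) whose
#' constructive-solid-geometry expression contains the point. Pure function of
#' its inputs.
#'
#' @param geom a `pd_geometry` (see [build_phantom()], [build_water_phantom()])
#' @param points numeric matrix (n x 3) or length-3 vector of coordinates, cm
#' @return character vector of cell labels; `"exterior"` where no cell claims
#'   the point
#' @export
locate <- function(geom, points) {
  stopifnot(inherits(geom, "pd_geometry"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  idx <- pd_cpp_locate(unclass(geom), points)
  out <- rep("exterior", nrow(points))
  out[idx > 0] <- geom$label[idx[idx > 0]]
  out
}

#' Trace a ray through a geometry
#'
#' Returns the ordered cell segments crossed by a ray, with exact parametric
#' start/end distances; segment lengths telescope so the accumulated length
#' equals the traversal length.
#'
#' @param geom a `pd_geometry`
#' @param origin length-3 start point (cm)
#' @param direction length-3 direction (normalized internally)
#' @param tmax maximum traced distance (cm)
#' @return tibble with `cell` (label), `t0`, `t1`, `length`
#' @export
trace_ray <- function(geom, origin, direction, tmax = 500) {
  m <- pd_cpp_trace(unclass(geom), origin, direction, tmax)
  lab <- c("exterior", geom$label)[m[, "cell"] + 1]
  tibble::tibble(
    cell = lab, t0 = m[, "t0"], t1 = m[, "t1"],
    length = m[, "t1"] - m[, "t0"]
  )
}

#' Audit pairwise cell disjointness by random point membership
#'
#' Samples points uniformly in a bounding box and counts how many cells claim
#' each; disjoint, gap-free geometry yields exactly one owner everywhere
#' inside the world sphere.
#'
#' @param geom a `pd_geometry`
#' @param n number of points
#' @param lower,upper bounding box corners (cm)
#' @param seed RNG seed
#' @return tibble with `n_points`, `n_double` (points claimed by >1 cell),
#'   `n_orphan` (points claimed by none)
#' @export
audit_geometry <- function(geom, n = 1e5, lower = c(-40, -25, -90),
                           upper = c(40, 25, 160), seed = 1) {
  set.seed(seed)
  pts <- cbind(
    stats::runif(n, lower[1], upper[1]),
    stats::runif(n, lower[2], upper[2]),
    stats::runif(n, lower[3], upper[3])
  )
  cnt <- pd_cpp_membership_count(unclass(geom), pts)
  tibble::tibble(
    n_points = n,
    n_double = sum(cnt > 1),
    n_orphan = sum(cnt == 0)
  )
}
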