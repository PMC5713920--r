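# Two-field tangential breast treatment: field construction, simulation and
# dose normalization.

PD_PRESCRIPTION_GY <- 50.4
PD_BORDER_MARGIN_CM <- 0.5 # clearance between border plane and contralateral breast

# unit source direction in the transverse plane for a gantry angle in degrees
# (0 deg = anterior, increasing toward the patient's left)
#' @noRd
.pd_gantry_dir <- function(gantry_deg) {
  c(sinpi(gantry_deg / 180), cospi(gantry_deg / 180), 0)
}

# transverse width direction as computed by beam_field() for axis d
#' @noRd
.pd_width_dir <- function(d) {
  u <- c(d[2], -d[1], 0)
  u / sqrt(sum(u^2))
}

#' Configure opposed tangential treatment fields
#'
#' Builds the medial and lateral fields of a two-field tangential plan for
#' the left breast. A small breast uses a 10 x 16 cm aperture with gantry
#' angles 286 deg (medial) and 115 deg (lateral); a large breast uses
#' 12 x 20 cm at 301 deg and 128 deg. Gantry 0 deg is anterior and angles
#' increase toward the patient's left; sources sit 100 cm from the aim point
#' in the transverse plane through the tumor.
#'
#' Because the two gantry angles differ from directly opposed by more than
#' the aperture divergence, the posterior field borders can only be matched
#' with width-asymmetric apertures. The shared posterior border plane is
#' constructed explicitly: it contains both sources and the vertical
#' direction, and the aim point is displaced anteriorly along the border
#' normal until the plane clears the contralateral breast by a fixed margin.
#' Each field's posterior width limit is then the aperture coordinate whose
#' edge ray lies in that plane, so the two posterior borders are coplanar by
#' construction (and the contralateral breast receives no primary fluence).
#'
#' @param phantom a phantom from [build_phantom()] (supplies the tumor
#'   location, breast centers and breast radius)
#' @param breast_size `"auto"` (from the phantom's breast volume),
#'   `"small"` or `"large"`
#' @param prescription_gy total prescribed tumor dose in Gy over both fields
#' @return a `pd_plan`: list with `fields` (medial and lateral
#'   [beam_field()]s), `gantry_deg`, `field_width_cm`, `field_height_cm`,
#'   `aim_point`, `border_normal`, `border_offset`, `breast_size`,
#'   `prescription_gy`
#' @export
configure_tangential_fields <- function(phantom,
                                        breast_size = c("auto", "small", "large"),
                                        prescription_gy = PD_PRESCRIPTION_GY) {
  stopifnot(inherits(phantom, "pd_geometry"))
  breast_size <- match.arg(breast_size)
  if (breast_size == "auto") {
    vol <- attr(phantom, "breast_volume")
    breast_size <- if (!is.null(vol) && vol > 500) "large" else "small"
  }
  if (breast_size == "small") {
    gantry <- c(medial = 286, lateral = 115)
    wd <- 10
    ht <- 16
  } else {
    gantry <- c(medial = 301, lateral = 128)
    wd <- 12
    ht <- 20
  }
  tumor <- attr(phantom, "tumor_center")
  contra <- attr(phantom, "breast_center_right")
  rb <- attr(phantom, "breast_radius")
  s_med <- .pd_gantry_dir(gantry[["medial"]])
  s_lat <- .pd_gantry_dir(gantry[["lateral"]])

  # border plane: contains both sources and the vertical; its horizontal
  # normal is perpendicular to the source-to-source chord
  chord <- s_lat - s_med
  nrm <- c(chord[2], -chord[1], 0)
  nrm <- nrm / sqrt(sum(nrm^2))
  if (sum(tumor * nrm) > sum(contra * nrm)) nrm <- -nrm # nrm points posterior
  # plane offset: tangent to the contralateral breast on its anterior side,
  # plus clearance; the open field lies on the anterior (smaller-value) side
  c_plane <- sum(contra * nrm) - rb - PD_BORDER_MARGIN_CM
  # displace the aim point along the normal so both sources lie in the plane
  # (s_lat . nrm == s_med . nrm because the chord is in the plane)
  aim <- tumor + (c_plane - PD_SAD_CM * sum(s_med * nrm) - sum(tumor * nrm)) * nrm

  make_field <- function(s_dir, label) {
    src <- aim + PD_SAD_CM * s_dir
    d <- -s_dir
    u <- .pd_width_dir(d)
    un <- sum(u * nrm)
    w_edge <- -PD_SAD_CM * sum(d * nrm) / un
    width <- sort(c(w_edge, w_edge - sign(un) * wd))
    fld <- beam_field(
      source = src, target = aim,
      width_limits = width, height_limits = c(-ht / 2, ht / 2),
      label = label
    )
    # the tumor must sit well inside the aperture
    vt <- tumor - src
    a1 <- PD_SAD_CM * sum(vt * u) / sum(vt * d)
    if (a1 < width[1] + 1 || a1 > width[2] - 1) {
      stop("tangential field '", label, "' does not cover the tumor site")
    }
    fld
  }

  plan <- list(
    fields = list(
      medial = make_field(s_med, "medial"),
      lateral = make_field(s_lat, "lateral")
    ),
    gantry_deg = gantry,
    field_width_cm = wd,
    field_height_cm = ht,
    aim_point = aim,
    border_normal = nrm,
    border_offset = c_plane,
    breast_size = breast_size,
    prescription_gy = prescription_gy
  )
  class(plan) <- "pd_plan"
  plan
}

#' @export
print.pd_plan <- function(x, ...) {
  cat(
    "<pd_plan> ", x$breast_size, " breast, ", x$field_width_cm, " x ",
    x$field_height_cm, " cm fields, gantry ", x$gantry_deg[["medial"]],
    " / ", x$gantry_deg[["lateral"]], " deg, ", x$prescription_gy,
    " Gy prescribed\n",
    sep = ""
  )
  ba <- border_alignment(x)
  cat(sprintf(
    "  posterior borders coplanar to %.2g mm at the isocenter plane\n",
    10 * ba
  ))
  invisible(x)
}

#' Posterior border alignment of a tangential plan
#'
#' Maximum distance (cm) between the two fields' posterior border planes,
#' evaluated at probe points on each border in the neighbourhood of the
#' isocenter plane.
#'
#' @param plan a `pd_plan`
#' @return maximum separation in cm
#' @export
border_alignment <- function(plan) {
  stopifnot(inherits(plan, "pd_plan"))
  edge_geom <- function(fld) {
    d <- fld$axis
    u <- fld$width_dir
    un <- sum(u * plan$border_normal)
    w_edge <- if (un > 0) max(fld$width_limits) else min(fld$width_limits)
    e <- d + (w_edge / PD_SAD_CM) * u
    e <- e / sqrt(sum(e^2))
    m <- c(e[2], -e[1], 0) # normal of the edge plane (contains e and z)
    list(src = fld$source, e = e, m = m / sqrt(sum(m^2)))
  }
  g1 <- edge_geom(plan$fields$medial)
  g2 <- edge_geom(plan$fields$lateral)
  sep <- function(a, b) {
    # probe points on border a near the phantom, around the isocenter height
    p <- lapply(c(90, 100, 110), function(t) {
      lapply(c(-10, 0, 10), function(dz) a$src + t * a$e + c(0, 0, dz))
    })
    max(vapply(
      unlist(p, recursive = FALSE),
      function(pt) abs(sum((pt - b$src) * b$m)), numeric(1)
    ))
  }
  max(sep(g1, g2), sep(g2, g1))
}

#' Simulate a two-field tangential treatment
#'
#' Transports both fields through the phantom and normalizes each field so
#' that it delivers half the prescribed dose to the tumor site (the
#' 0.5 cm radius sphere at the breast center). If the tumor tally of either
#' field has a relative error above 50% the run refuses to normalize.
#'
#' @param phantom a phantom from [build_phantom()]
#' @param plan a `pd_plan` from [configure_tangential_fields()]
#' @param n_histories number of source photons per field
#' @param seed integer seed (required); emission and transport seeds for the
#'   two fields are derived from it deterministically
#' @param spectra a `pd_beam_spectra`
#' @return a `pd_treatment` tibble: one row per cell with `cell`, `organ`,
#'   `material`, `mass_g`, `dose_medial_cgy`, `dose_lateral_cgy`,
#'   `dose_cgy`, `rel_err` (of the summed dose), `primary_medial`,
#'   `primary_lateral`, `in_beam` (any primary fluence from either open
#'   aperture). Attributes: `plan`, `seed`, `n_histories`, `tallies`,
#'   `tumor_rel_err`.
#' @export
run_treatment <- function(phantom, plan, n_histories = 2e5, seed,
                          spectra = beam_spectra()) {
  stopifnot(inherits(phantom, "pd_geometry"), inherits(plan, "pd_plan"))
  if (missing(seed)) stop("run_treatment() requires an explicit seed")
  n_histories <- as.integer(n_histories)
  presc_cgy <- 100 * plan$prescription_gy

  tallies <- vector("list", 2)
  names(tallies) <- names(plan$fields)
  for (i in 1:2) {
    set.seed(seed + i)
    ph <- emit_beam(plan$fields[[i]], n_histories, spectra)
    tallies[[i]] <- run_transport(phantom, ph, seed = seed + 100L + i)
  }

  it <- match("tumor", tallies[[1]]$cell)
  if (is.na(it)) stop("phantom has no 'tumor' cell")
  scale <- numeric(2)
  tum_re <- numeric(2)
  for (i in 1:2) {
    k <- tallies[[i]]$kerma_mev_g[it]
    re <- tallies[[i]]$kerma_rel_err[it]
    if (!is.finite(k) || k <= 0 || !is.finite(re) || re > 0.5) {
      stop(
        "tumor tally of the ", names(tallies)[i], " field is too uncertain ",
        "to normalize (relative error ",
        if (is.finite(re)) sprintf("%.0f%%", 100 * re) else "undefined",
        "); increase n_histories"
      )
    }
    scale[i] <- (presc_cgy / 2) / k
    tum_re[i] <- re
  }

  t1 <- tallies[[1]]
  t2 <- tallies[[2]]
  d1 <- t1$kerma_mev_g * scale[1]
  d2 <- t2$kerma_mev_g * scale[2]
  s1 <- ifelse(is.na(t1$kerma_rel_err), 0, d1 * t1$kerma_rel_err)
  s2 <- ifelse(is.na(t2$kerma_rel_err), 0, d2 * t2$kerma_rel_err)
  tot <- d1 + d2
  out <- tibble::tibble(
    cell = t1$cell,
    organ = t1$organ,
    material = t1$material,
    mass_g = t1$mass_g,
    dose_medial_cgy = d1,
    dose_lateral_cgy = d2,
    dose_cgy = tot,
    rel_err = ifelse(tot > 0, sqrt(s1^2 + s2^2) / tot, NA_real_),
    primary_medial = t1$primary_flux > 0,
    primary_lateral = t2$primary_flux > 0,
    in_beam = t1$primary_flux > 0 | t2$primary_flux > 0
  )
  class(out) <- c("pd_treatment", class(out))
  attr(out, "plan") <- plan
  attr(out, "seed") <- seed
  attr(out, "n_histories") <- n_histories
  attr(out, "tallies") <- tallies
  attr(out, "tumor_rel_err") <- tum_re
  out
}

#' @export
print.pd_treatment <- function(x, ...) {
  plan <- attr(x, "plan")
  cat(
    "<pd_treatment> ", plan$breast_size, " breast, ",
    attr(x, "n_histories"), " histories/field (seed ", attr(x, "seed"),
    ")\n  tumor dose ", format(x$dose_cgy[match("tumor", x$cell)]),
    " cGy, tumor tally rel. err. ",
    sprintf("%.1f%% / %.1f%%", 100 * attr(x, "tumor_rel_err")[1],
            100 * attr(x, "tumor_rel_err")[2]),
    " (medial/lateral)\n",
    sep = ""
  )
  NextMethod()
}

#' @rdname tidy_peridose
#' @export
tidy.pd_treatment <- function(x, ...) {
  tibble::as_tibble(x)[, c(
    "cell", "organ", "dose_medial_cgy", "dose_lateral_cgy", "dose_cgy",
    "rel_err", "in_beam"
  )]
}

#' @rdname tidy_peridose
#' @export
glance.pd_treatment <- function(x, ...) {
  plan <- attr(x, "plan")
  tibble::tibble(
    breast_size = plan$breast_size,
    prescription_gy = plan$prescription_gy,
    n_histories_per_field = attr(x, "n_histories"),
    tumor_dose_cgy = x$dose_cgy[match("tumor", x$cell)],
    tumor_rel_err = max(attr(x, "tumor_rel_err")),
    n_in_beam = sum(x$in_beam),
    border_separation_cm = border_alignment(plan)
  )
}

#' In-phantom point-dose verification along the abdominal chain
#'
#' Reads out the six 1 cm radius verification spheres embedded along the
#' phantom trunk at 15 to 40 cm below the isocenter plane (the simulated
#' counterpart of a thermoluminescent-dosimeter chain), and optionally
#' compares them with a reference measurement set.
#'
#' @param treatment a `pd_treatment` from [run_treatment()]
#' @param reference optional tibble with columns `distance_cm` and
#'   `dose_cgy` (e.g. from [generate_tld_fixture()])
#' @return tibble with `position` (cell name), `distance_cm` (below the
#'   isocenter plane), `dose_cgy`, `rel_err` and, when a reference is given,
#'   `reference_cgy` and `percent_diff`; attributes `mean_abs_percent_diff`
#'   and `sd_abs_percent_diff` summarize the paired comparison
#' @export
run_tld_verification <- function(treatment, reference = NULL) {
  stopifnot(inherits(treatment, "pd_treatment"))
  cells <- paste0("tld_", 1:6)
  i <- match(cells, treatment$cell)
  if (anyNA(i)) stop("phantom lacks the tld_1..tld_6 verification cells")
  plan <- attr(treatment, "plan")
  iso_z <- plan$aim_point[3]
  tld_z <- c(37, 32, 27, 22, 17, 12)
  out <- tibble::tibble(
    position = cells,
    distance_cm = iso_z - tld_z,
    dose_cgy = treatment$dose_cgy[i],
    rel_err = treatment$rel_err[i]
  )
  if (!is.null(reference)) {
    j <- match(round(out$distance_cm), round(reference$distance_cm))
    out$reference_cgy <- reference$dose_cgy[j]
    out$percent_diff <- ifelse(
      out$reference_cgy > 0,
      100 * (out$dose_cgy - out$reference_cgy) / out$reference_cgy,
      NA_real_
    )
    attr(out, "mean_abs_percent_diff") <- mean(abs(out$percent_diff),
      na.rm = TRUE
    )
    attr(out, "sd_abs_percent_diff") <- stats::sd(abs(out$percent_diff),
      na.rm = TRUE
    )
  }
  out
}
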