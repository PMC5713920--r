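# MIRD-style humanoid phantom built from quadric cells.
#
# Coordinates: origin at the center of the trunk base, +z toward the head,
# +x toward the patient's left, +y anterior. Lengths in cm, masses in g.

# ellipsoid volume above a plane cutting the ellipsoid at fraction
# zeta = (z_plane - center)/semi_c of the polar semi-axis
#' @noRd
.pd_ellipsoid_cap <- function(a, b, c, zeta) {
  zeta <- max(-1, min(1, zeta))
  pi * a * b * c * (2 / 3 - zeta + zeta^3 / 3)
}

# area of an ellipse (semi-axes a, b, center cy in y) restricted to y > y0
#' @noRd
.pd_ellipse_area_above <- function(a, b, cy, y0) {
  eta <- max(-1, min(1, (y0 - cy) / b))
  a * b * (acos(eta) - eta * sqrt(1 - eta^2))
}

# numeric volume of a breast: sphere of radius r centered on the trunk
# surface, restricted to the outside of the trunk ellipse (and optionally to
# the outside of the mirror sphere, for the side that yields on overlap)
#' @noRd
.pd_breast_volume <- function(center, r, trunk_a, trunk_b,
                              exclude_center = NULL, nz = 81, nxy = 121) {
  zs <- seq(center[3] - r, center[3] + r, length.out = nz)
  xs <- seq(center[1] - r, center[1] + r, length.out = nxy)
  ys <- seq(center[2] - r, center[2] + r, length.out = nxy)
  dz <- zs[2] - zs[1]
  dx <- xs[2] - xs[1]
  dy <- ys[2] - ys[1]
  gx <- rep(xs, times = nxy)
  gy <- rep(ys, each = nxy)
  outside <- (gx / trunk_a)^2 + (gy / trunk_b)^2 > 1
  vol <- 0
  for (z in zs) {
    rho2 <- r^2 - (z - center[3])^2
    if (rho2 <= 0) next
    inside <- (gx - center[1])^2 + (gy - center[2])^2 < rho2 & outside
    if (!is.null(exclude_center)) {
      rho2m <- r^2 - (z - exclude_center[3])^2
      if (rho2m > 0) {
        inside <- inside &
          (gx - exclude_center[1])^2 + (gy - exclude_center[2])^2 >= rho2m
      }
    }
    vol <- vol + sum(inside) * dx * dy * dz
  }
  vol
}

# overlap volume of two axis-aligned ellipsoids by grid quadrature
#' @noRd
.pd_ellipsoid_overlap <- function(c1, s1, c2, s2, n = 101) {
  lo <- pmax(c1 - s1, c2 - s2)
  hi <- pmin(c1 + s1, c2 + s2)
  if (any(hi <= lo)) {
    return(0)
  }
  gx <- seq(lo[1], hi[1], length.out = n)
  gy <- seq(lo[2], hi[2], length.out = n)
  gz <- seq(lo[3], hi[3], length.out = n)
  dv <- prod(hi - lo) / (n - 1)^3
  g <- expand.grid(x = gx, y = gy, z = gz)
  in1 <- ((g$x - c1[1]) / s1[1])^2 + ((g$y - c1[2]) / s1[2])^2 +
    ((g$z - c1[3]) / s1[3])^2 < 1
  in2 <- ((g$x - c2[1]) / s2[1])^2 + ((g$y - c2[2]) / s2[2])^2 +
    ((g$z - c2[3]) / s2[3])^2 < 1
  sum(in1 & in2) * dv
}

# breast radius whose protruding volume matches a target (cm^3)
#' @noRd
.pd_breast_radius <- function(volume, center_x, trunk_a, trunk_b, center_z) {
  f <- function(r) {
    cy <- trunk_b * sqrt(1 - (center_x / trunk_a)^2)
    .pd_breast_volume(c(center_x, cy, center_z), r, trunk_a, trunk_b) - volume
  }
  stats::uniroot(f, c(1, 15), tol = 1e-4)$root
}

#' Red bone marrow site fractions
#'
#' Fractional distribution of the active (red) bone marrow over skeletal
#' sites, mapped onto the phantom's bone cells. Sites whose bone lies in the
#' primary beam are excluded (with renormalization) by the reporting layer.
#'
#' @return tibble with `site`, `fraction` (sums to 1) and `bone_organ` (the
#'   organ label of the phantom bone cells representing the site)
#' @export
rbm_site_table <- function() {
  tibble::tibble(
    site = c("cranium", "spine", "ribcage", "shoulder_girdle", "pelvis", "legs"),
    fraction = c(0.084, 0.323, 0.228, 0.023, 0.274, 0.068),
    bone_organ = c(
      "bone_skull", "bone_spine", "bone_ribs", "bone_ribs",
      "bone_pelvis", "bone_legs"
    )
  )
}

#' Lymph node cluster weights
#'
#' Fractional lymph-node volume per cluster and the phantom region whose dose
#' represents the cluster: either a mass-weighted organ dose or dedicated
#' small tally cells placed in lymphoid regions (axilla, upper pelvis, upper
#' leg muscle).
#'
#' @return tibble with `cluster`, `weight` (percent of total lymph volume)
#'   and `region` (organ label or tally-cell prefix)
#' @export
lymph_cluster_table <- function() {
  tibble::tibble(
    cluster = c(
      "head_neck_glandular", "head_neck_soft_tissue", "chest", "axilla",
      "abdomen_stomach", "abdomen_small_intestine", "pelvis", "upper_leg"
    ),
    weight = c(1, 24.1, 8.8, 6, 2.5, 41.1, 13.5, 3),
    region = c(
      "parotid_thyroid", "et_tissue", "heart", "lymph_axilla",
      "stomach", "small_intestine", "lymph_pelvis", "lymph_leg"
    )
  )
}

#' Build the humanoid phantom
#'
#' Constructs the hermaphrodite mathematical phantom (height 179 cm, mass
#' about 73.5 kg) as a constructive-solid-geometry cell set: trunk with 0.2 cm
#' skin, rib cage, spine, pelvis and skull bone shells, internal organs,
#' breasts of parameterized volume attached to the anterior chest wall, a
#' spherical tumor inside the left breast, head, neck, legs, a raised left
#' arm (its bone replaced by soft tissue), small lymph-node tally cells and a
#' chain of six thermoluminescent-dosimeter cells along the abdomen at 5 cm
#' spacing below the treated region.
#'
#' @param breast_volume protruding breast volume in cm^3 per breast; the
#'   default 168.5 is the standard breast, 1354.4 the large breast
#' @return a `pd_geometry`; cells carry organ labels used by the reporting
#'   layer, and attributes `tumor_center` and `breast_radius`
#' @examples
#' \donttest{
#' ph <- build_phantom()
#' locate(ph, c(0, 0, 50))
#' }
#' @export
build_phantom <- function(breast_volume = 168.5) {
  ta <- 19; tb <- 9.5          # trunk outer semi-axes
  sk <- 0.2                    # skin thickness
  tia <- ta - sk; tib <- tb - sk
  gb <- .gb_new()
  st <- "soft_tissue"

  # ---- breasts and tumor ----------------------------------------------------
  bx <- 8
  bz <- 52
  by <- tb * sqrt(1 - (bx / ta)^2)
  rb <- .pd_breast_radius(breast_volume, bx, ta, tb, bz)
  nrm <- c(bx / ta^2, by / tb^2, 0)
  nrm <- nrm / sqrt(sum(nrm^2))
  tumor_c <- c(bx, by, bz) + 0.465 * rb * nrm
  trunk_out <- .sq_ezcyl(0, 0, ta, tb)
  .gb_cell(gb, "tumor",
    inside = list(.sq_sphere(tumor_c, 0.5)),
    material = st, volume = 4 / 3 * pi * 0.5^3, organ = "tumor"
  )
  v_bl <- .pd_breast_volume(c(bx, by, bz), rb, ta, tb)
  .gb_cell(gb, "left_breast",
    inside = list(.sq_sphere(c(bx, by, bz), rb)), outside = list(trunk_out),
    material = st, volume = v_bl - 4 / 3 * pi * 0.5^3,
    organ = "breast_ipsilateral", excludes = "tumor"
  )
  v_br <- .pd_breast_volume(c(-bx, by, bz), rb, ta, tb,
    exclude_center = c(bx, by, bz)
  )
  .gb_cell(gb, "right_breast",
    inside = list(.sq_sphere(c(-bx, by, bz), rb)), outside = list(trunk_out),
    material = st, volume = v_br, organ = "breast",
    excludes = "left_breast"
  )

  # ---- trunk skin and skeleton ---------------------------------------------
  trunk_in <- .sq_ezcyl(0, 0, tia, tib)
  z0 <- .sq_plane("z", 0); z70 <- .sq_plane("z", 70)
  .gb_cell(gb, "skin_trunk",
    inside = list(trunk_out, z70), outside = list(trunk_in, z0),
    material = st, volume = pi * (ta * tb - tia * tib) * 70,
    organ = "skin_trunk"
  )
  ribs_out <- .sq_ezcyl(0, 0, 16.3, 8)
  ribs_in <- .sq_ezcyl(0, 0, 15.8, 7.5)
  z42 <- .sq_plane("z", 42); z68 <- .sq_plane("z", 68)
  .gb_cell(gb, "ribs",
    inside = list(ribs_out, z68), outside = list(ribs_in, z42),
    material = "bone", volume = pi * (16.3 * 8 - 15.8 * 7.5) * 26,
    organ = "bone_ribs"
  )
  z12 <- .sq_plane("z", 12)
  .gb_cell(gb, "spine",
    inside = list(.sq_ezcyl(0, -5.3, 1.8, 1.8), z70), outside = list(z12),
    material = "bone", volume = pi * 1.8^2 * 58, organ = "bone_spine"
  )
  .gb_cell(gb, "pelvis_bone",
    inside = list(.sq_ezcyl(0, 0, 17, 8), z12, .sq_plane("y", 0)),
    outside = list(.sq_ezcyl(0, 0, 15.5, 6.5), z0),
    material = "bone", volume = 0.5 * pi * (17 * 8 - 15.5 * 6.5) * 12,
    organ = "bone_pelvis"
  )

  # ---- chest organs ---------------------------------------------------------
  .gb_cell(gb, "esophagus",
    inside = list(.sq_ezcyl(-1, -2.7, 0.8, 0.8), z70), outside = list(z42),
    material = st, volume = pi * 0.8^2 * 28, organ = "esophagus"
  )
  .gb_cell(gb, "heart",
    inside = list(.sq_ellipsoid(c(2.5, 2.5, 50), c(5, 4, 5))),
    material = st, volume = 4 / 3 * pi * 5 * 4 * 5, organ = "heart"
  )
  v_heart_lung <- .pd_ellipsoid_overlap(
    c(2.5, 2.5, 50), c(5, 4, 5), c(8.5, 0, 54), c(4.5, 5.5, 11)
  )
  .gb_cell(gb, "left_lung",
    inside = list(.sq_ellipsoid(c(8.5, 0, 54), c(4.5, 5.5, 11))),
    material = "lung", volume = 4 / 3 * pi * 4.5 * 5.5 * 11 - v_heart_lung,
    organ = "lung_left", excludes = "heart"
  )
  .gb_cell(gb, "right_lung",
    inside = list(.sq_ellipsoid(c(-8.5, 0, 54), c(4.5, 5.5, 11))),
    material = "lung", volume = 4 / 3 * pi * 4.5 * 5.5 * 11, organ = "lung"
  )
  .gb_cell(gb, "thymus",
    inside = list(.sq_ellipsoid(c(0.5, 5.5, 62), c(3, 1.5, 4))),
    material = st, volume = 4 / 3 * pi * 3 * 1.5 * 4, organ = "thymus"
  )
  for (s in c(1, -1)) {
    .gb_cell(gb, paste0("lymph_axilla_", if (s > 0) "l" else "r"),
      inside = list(.sq_sphere(c(s * 13, 1.5, 65), 1)),
      material = st, volume = 4 / 3 * pi, organ = "lymph_tally"
    )
  }

  # ---- TLD chain (5 cm spacing, 15-40 cm below the field border) ------------
  tld_z <- c(37, 32, 27, 22, 17, 12)
  tld_y <- c(0, -0.5, 0, 0, 0, 0)
  for (i in seq_along(tld_z)) {
    .gb_cell(gb, paste0("tld_", i),
      inside = list(.sq_sphere(c(-4, tld_y[i], tld_z[i]), 1)),
      material = st, volume = 4 / 3 * pi, organ = "tld"
    )
  }

  # ---- abdominal organs -----------------------------------------------------
  v_sph <- 4 / 3 * pi
  .gb_cell(gb, "liver",
    inside = list(.sq_ellipsoid(c(-7.5, 0.5, 36), c(10, 6, 6.5))),
    material = st, volume = 4 / 3 * pi * 10 * 6 * 6.5 - 2 * v_sph,
    organ = "liver", excludes = c("tld_1", "tld_2")
  )
  .gb_cell(gb, "stomach",
    inside = list(.sq_ellipsoid(c(7, 2, 35.5), c(3.5, 3, 6))),
    material = st, volume = 4 / 3 * pi * 3.5 * 3 * 6, organ = "stomach"
  )
  .gb_cell(gb, "spleen",
    inside = list(.sq_ellipsoid(c(13, -3, 36), c(3, 2.5, 5))),
    material = st, volume = 4 / 3 * pi * 3 * 2.5 * 5, organ = "spleen"
  )
  .gb_cell(gb, "pancreas",
    inside = list(.sq_ellipsoid(c(0, -1.8, 28.5), c(6, 1.5, 1.5))),
    material = st, volume = 4 / 3 * pi * 6 * 1.5 * 1.5, organ = "pancreas"
  )
  for (s in c(1, -1)) {
    .gb_cell(gb, paste0("kidney_", if (s > 0) "l" else "r"),
      inside = list(.sq_ellipsoid(c(s * 6.5, -6, 25), c(2, 2.6, 5))),
      material = st, volume = 4 / 3 * pi * 2 * 2.6 * 5, organ = "kidneys"
    )
    .gb_cell(gb, paste0("adrenal_", if (s > 0) "l" else "r"),
      inside = list(.sq_ellipsoid(c(s * 6, -6.8, 32.5), c(1.5, 1, 2))),
      material = st, volume = 4 / 3 * pi * 1.5 * 1 * 2, organ = "adrenals"
    )
  }
  .gb_cell(gb, "gall_bladder",
    inside = list(.sq_ellipsoid(c(-4, 4.5, 28), c(1.5, 1, 1.5))),
    material = st, volume = 4 / 3 * pi * 1.5 * 1 * 1.5, organ = "gall_bladder"
  )
  si_ell <- .sq_ezcyl(0, 1.5, 9, 4.5)
  z14 <- .sq_plane("z", 14); z26 <- .sq_plane("z", 26)
  .gb_cell(gb, "small_intestine",
    inside = list(si_ell, z26), outside = list(z14),
    material = st, volume = pi * 9 * 4.5 * 12 - 2 * v_sph,
    organ = "small_intestine", excludes = c("tld_4", "tld_5")
  )
  z195 <- .sq_plane("z", 19.5)
  colon_area <- .pd_ellipse_area_above(12, 6.5, 1.5, -2) -
    .pd_ellipse_area_above(9, 4.5, 1.5, -2)
  .gb_cell(gb, "colon",
    inside = list(.sq_ezcyl(0, 1.5, 12, 6.5), z195),
    outside = list(si_ell, z14, .sq_plane("y", -2)),
    material = st, volume = colon_area * 5.5, organ = "colon"
  )

  # ---- pelvic organs --------------------------------------------------------
  .gb_cell(gb, "bladder",
    inside = list(.sq_ellipsoid(c(0, 2, 5), c(3.5, 3, 2.5))),
    material = st, volume = 4 / 3 * pi * 3.5 * 3 * 2.5, organ = "bladder"
  )
  .gb_cell(gb, "uterus",
    inside = list(.sq_ellipsoid(c(0, -1, 10.5), c(2.5, 1.5, 3.5))),
    material = st, volume = 4 / 3 * pi * 2.5 * 1.5 * 3.5, organ = "uterus"
  )
  for (s in c(1, -1)) {
    .gb_cell(gb, paste0("ovary_", if (s > 0) "l" else "r"),
      inside = list(.sq_ellipsoid(c(s * 5, -1, 10), c(1, 0.75, 1.5))),
      material = st, volume = 4 / 3 * pi * 1 * 0.75 * 1.5, organ = "ovaries"
    )
    .gb_cell(gb, paste0("lymph_pelvis_", if (s > 0) "l" else "r"),
      inside = list(.sq_sphere(c(s * 6, -3, 12), 1)),
      material = st, volume = 4 / 3 * pi, organ = "lymph_tally"
    )
  }

  # ---- trunk residual soft tissue ------------------------------------------
  v_liver_r1 <- .pd_ellipsoid_cap(10, 6, 6.5, (42 - 36) / 6.5)
  .gb_cell(gb, "mediastinum",
    inside = list(ribs_in, z68), outside = list(z42),
    material = st,
    volume = pi * 15.8 * 7.5 * 26 -
      (2 * (4 / 3 * pi * 4.5 * 5.5 * 11 - 130.2) + 130.2) - # lungs less heart overlap
      4 / 3 * pi * 5 * 4 * 5 - 4 / 3 * pi * 3 * 1.5 * 4 -   # heart, thymus
      pi * 0.8^2 * 26 - pi * 1.8^2 * 26 -                   # esophagus, spine
      2 * v_sph - v_liver_r1,                               # axilla nodes, liver tip
    organ = "muscle",
    excludes = c(
      "left_lung", "right_lung", "heart", "thymus", "esophagus", "spine",
      "lymph_axilla_l", "lymph_axilla_r", "liver"
    )
  )
  .gb_cell(gb, "chest_wall",
    inside = list(trunk_in, z68), outside = list(ribs_out, z42),
    material = st, volume = pi * (tia * tib - 16.3 * 8) * 26,
    organ = "chest_wall"
  )
  .gb_cell(gb, "shoulder_band",
    inside = list(trunk_in, z70), outside = list(z68),
    material = st,
    volume = pi * tia * tib * 2 - pi * 0.8^2 * 2 - pi * 1.8^2 * 2,
    organ = "muscle", excludes = c("spine", "esophagus")
  )
  v_ut_above <- .pd_ellipsoid_cap(2.5, 1.5, 3.5, (12 - 10.5) / 3.5)
  v_ut <- 4 / 3 * pi * 2.5 * 1.5 * 3.5
  .gb_cell(gb, "abdomen_tissue",
    inside = list(trunk_in, z42), outside = list(z12),
    material = st,
    volume = pi * tia * tib * 30 -
      (4 / 3 * pi * 10 * 6 * 6.5 - v_liver_r1) -            # liver below z=42
      4 / 3 * pi * (3.5 * 3 * 6 + 3 * 2.5 * 5 + 6 * 1.5 * 1.5 +
        2 * 2 * 2.6 * 5 + 2 * 1.5 * 1 * 2 + 1.5 * 1 * 1.5) -
      pi * 9 * 4.5 * 12 - colon_area * 5.5 -                # SI (raw), colon
      v_ut_above - pi * 1.8^2 * 30 -                        # uterus tip, spine
      v_sph - 0.5 * v_sph -                                 # tld_3, tld_6 half
      0.5 * v_sph * 2,                                      # pelvic node halves
    organ = "muscle",
    excludes = c(
      "liver", "stomach", "spleen", "pancreas", "kidney_l", "kidney_r",
      "adrenal_l", "adrenal_r", "gall_bladder", "small_intestine", "colon",
      "uterus", "spine", "tld_3", "tld_6", "lymph_pelvis_l", "lymph_pelvis_r"
    )
  )
  .gb_cell(gb, "pelvis_tissue",
    inside = list(trunk_in, z12), outside = list(z0),
    material = st,
    volume = pi * tia * tib * 12 - 0.5 * pi * (17 * 8 - 15.5 * 6.5) * 12 -
      4 / 3 * pi * 3.5 * 3 * 2.5 - (v_ut - v_ut_above) -
      2 * 4 / 3 * pi * 1 * 0.75 * 1.5 - 0.5 * v_sph * 2 - 0.5 * v_sph,
    organ = "muscle",
    excludes = c(
      "pelvis_bone", "bladder", "uterus", "ovary_l", "ovary_r",
      "lymph_pelvis_l", "lymph_pelvis_r", "tld_6"
    )
  )

  # ---- neck -----------------------------------------------------------------
  z79 <- .sq_plane("z", 79)
  .gb_cell(gb, "thyroid",
    inside = list(.sq_ellipsoid(c(0, 3, 72.5), c(2.2, 1.2, 2))),
    material = st, volume = 4 / 3 * pi * 2.2 * 1.2 * 2, organ = "thyroid"
  )
  .gb_cell(gb, "neck_core",
    inside = list(.sq_ezcyl(0, 0, 5.3, 5.3), z79), outside = list(z70),
    material = st, volume = pi * 5.3^2 * 9 - 4 / 3 * pi * 2.2 * 1.2 * 2,
    organ = "et_tissue", excludes = "thyroid"
  )
  .gb_cell(gb, "skin_neck",
    inside = list(.sq_ezcyl(0, 0, 5.5, 5.5), z79),
    outside = list(.sq_ezcyl(0, 0, 5.3, 5.3), z70),
    material = st, volume = pi * (5.5^2 - 5.3^2) * 9, organ = "skin"
  )

  # ---- head -----------------------------------------------------------------
  z91 <- .sq_plane("z", 91)
  skull_out <- .sq_ellipsoid(c(0, 0.5, 91), c(6.6, 8.6, 6.1))
  brain_ell <- .sq_ellipsoid(c(0, 0.5, 91), c(6, 8, 5.5))
  .gb_cell(gb, "brain",
    inside = list(brain_ell),
    material = st, volume = 4 / 3 * pi * 6 * 8 * 5.5, organ = "brain"
  )
  .gb_cell(gb, "skull",
    inside = list(skull_out), outside = list(brain_ell),
    material = "bone",
    volume = 4 / 3 * pi * (6.6 * 8.6 * 6.1 - 6 * 8 * 5.5), organ = "bone_skull"
  )
  sal <- list(
    parotid_l = list(c(5.5, -1, 84), 1.2), parotid_r = list(c(-5.5, -1, 84), 1.2),
    submandibular_l = list(c(3.2, 2.8, 80), 0.9),
    submandibular_r = list(c(-3.2, 2.8, 80), 0.9),
    sublingual = list(c(0, 5.8, 80), 0.7)
  )
  for (nm in names(sal)) {
    .gb_cell(gb, nm,
      inside = list(.sq_sphere(sal[[nm]][[1]], sal[[nm]][[2]])),
      material = st, volume = 4 / 3 * pi * sal[[nm]][[2]]^3,
      organ = "salivary_glands"
    )
  }
  .gb_cell(gb, "oral_mucosa",
    inside = list(.sq_ellipsoid(c(0, 3.8, 82.6), c(2.5, 2, 1.3))),
    material = st, volume = 4 / 3 * pi * 2.5 * 2 * 1.3, organ = "oral_mucosa"
  )
  head_in <- .sq_ezcyl(0, 0, 6.8, 9.3)
  v_skull <- 4 / 3 * pi * (6.6 * 8.6 * 6.1 - 6 * 8 * 5.5)
  v_brain <- 4 / 3 * pi * 6 * 8 * 5.5
  v_sal <- 4 / 3 * pi * (2 * 1.2^3 + 2 * 0.9^3 + 0.7^3)
  .gb_cell(gb, "head_core",
    inside = list(head_in, z91), outside = list(z79),
    material = st,
    volume = pi * 6.8 * 9.3 * 12 - v_skull / 2 - v_brain / 2 - v_sal -
      4 / 3 * pi * 2.5 * 2 * 1.3,
    organ = "muscle",
    excludes = c("brain", "skull", names(sal), "oral_mucosa")
  )
  cap_in <- .sq_ellipsoid(c(0, 0, 91), c(6.8, 9.3, 7.8))
  .gb_cell(gb, "head_cap_core",
    inside = list(cap_in), outside = list(z91),
    material = st,
    volume = 2 / 3 * pi * 6.8 * 9.3 * 7.8 - v_skull / 2 - v_brain / 2,
    organ = "muscle", excludes = c("brain", "skull")
  )
  head_out <- .sq_ezcyl(0, 0, 7, 9.5)
  .gb_cell(gb, "skin_head",
    inside = list(head_out, z91), outside = list(head_in, z79),
    material = st, volume = pi * (7 * 9.5 - 6.8 * 9.3) * 12, organ = "skin"
  )
  .gb_cell(gb, "skin_head_cap",
    inside = list(.sq_ellipsoid(c(0, 0, 91), c(7, 9.5, 8))),
    outside = list(cap_in, z91),
    material = st, volume = 2 / 3 * pi * (7 * 9.5 * 8 - 6.8 * 9.3 * 7.8),
    organ = "skin"
  )

  # ---- raised left arm ------------------------------------------------------
  z140 <- .sq_plane("z", 140)
  arm_in <- .sq_ezcyl(12, 0, 4.3, 4.3)
  arm_out <- .sq_ezcyl(12, 0, 4.5, 4.5)
  .gb_cell(gb, "arm_core",
    inside = list(arm_in, z140), outside = list(z70),
    material = st, volume = pi * 4.3^2 * 70, organ = "muscle"
  )
  .gb_cell(gb, "arm_cap_core",
    inside = list(.sq_sphere(c(12, 0, 140), 4.3)), outside = list(z140),
    material = st, volume = 2 / 3 * pi * 4.3^3, organ = "muscle"
  )
  .gb_cell(gb, "skin_arm",
    inside = list(arm_out, z140), outside = list(arm_in, z70),
    material = st, volume = pi * (4.5^2 - 4.3^2) * 70, organ = "skin"
  )
  .gb_cell(gb, "skin_arm_cap",
    inside = list(.sq_sphere(c(12, 0, 140), 4.5)),
    outside = list(.sq_sphere(c(12, 0, 140), 4.3), z140),
    material = st, volume = 2 / 3 * pi * (4.5^3 - 4.3^3), organ = "skin"
  )

  # ---- legs -----------------------------------------------------------------
  r_top <- 8.8; r_bot <- 3.7; leg_h <- 80
  m <- (r_top - r_bot) / leg_h
  zm80 <- .sq_plane("z", -80)
  v_frustum <- function(r1, r2) pi * leg_h / 3 * (r1^2 + r1 * r2 + r2^2)
  for (s in c(1, -1)) {
    sfx <- if (s > 0) "l" else "r"
    .gb_cell(gb, paste0("leg_bone_", sfx),
      inside = list(.sq_ezcyl(s * 10, 0, 1.8, 1.8), z0), outside = list(zm80),
      material = "bone", volume = pi * 1.8^2 * leg_h, organ = "bone_legs"
    )
    .gb_cell(gb, paste0("lymph_leg_", sfx),
      inside = list(.sq_sphere(c(s * 13, 1.5, -20), 1)),
      material = st, volume = 4 / 3 * pi, organ = "lymph_tally"
    )
    .gb_cell(gb, paste0("leg_core_", sfx),
      inside = list(.sq_zcone(s * 10, 0, r_top - sk, 0, m), z0),
      outside = list(zm80),
      material = st,
      volume = v_frustum(r_top - sk, r_bot - sk) - pi * 1.8^2 * leg_h -
        4 / 3 * pi,
      organ = "muscle",
      excludes = paste0(c("leg_bone_", "lymph_leg_"), sfx)
    )
    .gb_cell(gb, paste0("skin_leg_", sfx),
      inside = list(.sq_zcone(s * 10, 0, r_top, 0, m), z0),
      outside = list(.sq_zcone(s * 10, 0, r_top - sk, 0, m), zm80),
      material = st,
      volume = v_frustum(r_top, r_bot) - v_frustum(r_top - sk, r_bot - sk),
      organ = "skin"
    )
  }

  geom <- .gb_finalize(gb)
  attr(geom, "tumor_center") <- tumor_c
  attr(geom, "breast_radius") <- rb
  attr(geom, "breast_center_left") <- c(bx, by, bz)
  attr(geom, "breast_center_right") <- c(-bx, by, bz)
  attr(geom, "breast_volume") <- breast_volume
  attr(geom, "tld_centers") <- cbind(
    x = rep(-4, length(tld_z)), y = tld_y, z = tld_z
  )
  geom
}
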