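# Organ dose aggregation and reporting for the tangential treatment study.

# reporting organ <-> phantom organ label(s); NULL sources are handled by
# dedicated estimators (red bone marrow, bone surface, lymphatic nodes)
#' @noRd
.pd_report_organs <- function() {
  tibble::tibble(
    organ = c(
      "breast", "stomach", "esophagus", "thyroid", "liver",
      "red_bone_marrow", "lung", "bone_surface", "salivary_glands", "colon",
      "skin", "brain", "ovaries", "urinary_bladder",
      "heart", "thymus", "pancreas", "spleen", "lymphatic_nodes", "adrenals",
      "gall_bladder", "extra_thoracic_tissue", "kidneys", "oral_mucosa",
      "small_intestine", "uterus", "muscle"
    ),
    group = rep(c("main", "remainder"), c(14, 13)),
    label = c(
      "breast", "stomach", "esophagus", "thyroid", "liver",
      NA, "lung", NA, "salivary_glands", "colon",
      "skin", "brain", "ovaries", "bladder",
      "heart", "thymus", "pancreas", "spleen", NA, "adrenals",
      "gall_bladder", "et_tissue", "kidneys", "oral_mucosa",
      "small_intestine", "uterus", "muscle"
    )
  )
}

# round half away from zero (base round() rounds half to even)
#' @noRd
.pd_round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# mass-weighted mean dose (and propagated relative error) over a set of
# treatment rows, after dropping cells flagged in-beam; all cells excluded
# yields NA, never a silent zero
#' @noRd
.pd_mass_weighted <- function(rows, dose_col, err_col = "rel_err") {
  keep <- !rows$in_beam
  if (!any(keep)) {
    return(list(dose = NA_real_, rel_err = NA_real_, n_cells = 0L))
  }
  m <- rows$mass_g[keep]
  d <- rows[[dose_col]][keep]
  re <- rows[[err_col]][keep]
  dose <- sum(m * d) / sum(m)
  abs_err <- sqrt(sum((m * d * ifelse(is.na(re), 0, re))^2)) / sum(m)
  list(
    dose = dose,
    rel_err = if (dose > 0) abs_err / dose else NA_real_,
    n_cells = sum(keep)
  )
}

#' Red bone marrow dose
#'
#' Mass-fraction-weighted mean over the active marrow sites, converting each
#' site's bone-cell dose to a marrow dose with the tissue-to-bone ratio of
#' mass energy absorption coefficients at the beam's mean energy. Sites whose
#' surrogate bone cells lie in the primary beam (the rib cage, and the
#' shoulder girdle which shares the rib cells) are excluded and the remaining
#' site fractions renormalized.
#'
#' @param treatment a `pd_treatment`
#' @param dose_col which dose column to aggregate (`"dose_cgy"`,
#'   `"dose_medial_cgy"` or `"dose_lateral_cgy"`)
#' @param energy_mev photon energy for the absorption-coefficient ratio
#'   (default: the mean energy of the bundled beam spectra)
#' @param exclude_sites marrow sites dropped from the weighted mean
#' @return dose in the units of `dose_col`
#' @export
rbm_dose <- function(treatment, dose_col = "dose_cgy",
                     energy_mev = beam_mean_energy(beam_spectra()),
                     exclude_sites = c("ribcage", "shoulder_girdle")) {
  stopifnot(inherits(treatment, "pd_treatment"))
  sites <- rbm_site_table()
  sites <- sites[!sites$site %in% exclude_sites, ]
  ratio <- muen_ratio("soft_tissue", "bone", energy_mev)
  d <- vapply(sites$bone_organ, function(org) {
    w <- .pd_mass_weighted(treatment[treatment$organ == org, ], dose_col)
    w$dose
  }, numeric(1))
  sum(sites$fraction * d * ratio) / sum(sites$fraction)
}

#' Bone surface dose
#'
#' Mass-weighted mean dose over the skeleton excluding the rib cage (which
#' is traversed by the primary beam).
#'
#' @inheritParams rbm_dose
#' @return dose in the units of `dose_col`
#' @export
bone_surface_dose <- function(treatment, dose_col = "dose_cgy") {
  stopifnot(inherits(treatment, "pd_treatment"))
  rows <- treatment[
    treatment$organ %in% c("bone_skull", "bone_spine", "bone_pelvis", "bone_legs"),
  ]
  .pd_mass_weighted(rows, dose_col)$dose
}

#' Lymphatic node dose
#'
#' Weighted mean over the node clusters of [lymph_cluster_table()], each
#' cluster represented by the dose to its surrogate region (a dedicated node
#' tally cell or a neighbouring organ).
#'
#' @inheritParams rbm_dose
#' @return dose in the units of `dose_col`
#' @export
lymph_node_dose <- function(treatment, dose_col = "dose_cgy") {
  stopifnot(inherits(treatment, "pd_treatment"))
  clusters <- lymph_cluster_table()
  region_dose <- function(region) {
    rows <- switch(region,
      parotid_thyroid = treatment[
        treatment$cell %in% c("parotid_l", "parotid_r", "thyroid"),
      ],
      et_tissue = treatment[treatment$organ == "et_tissue", ],
      lymph_axilla = treatment[
        treatment$cell %in% c("lymph_axilla_l", "lymph_axilla_r"),
      ],
      lymph_pelvis = treatment[
        treatment$cell %in% c("lymph_pelvis_l", "lymph_pelvis_r"),
      ],
      lymph_leg = treatment[
        treatment$cell %in% c("lymph_leg_l", "lymph_leg_r"),
      ],
      treatment[treatment$organ == region, ]
    )
    .pd_mass_weighted(rows, dose_col)$dose
  }
  d <- vapply(clusters$region, region_dose, numeric(1))
  sum(clusters$weight * d) / sum(clusters$weight)
}

#' Aggregate a treatment into an organ dose table
#'
#' Mass-weighted mean doses for the 27 reporting organs, per field and
#' total. Cells flagged in-beam (nonzero uncollided fluence from either open
#' aperture) are excluded from every organ mean; organs whose cells are all
#' in-beam get `NA` with a note, never a silent zero. Structures that belong
#' to the treated volume (tumor, ipsilateral breast, chest wall, trunk skin)
#' or that serve as laterality surrogates (the left lung; the reported lung
#' is the contralateral one) have distinct labels and never enter a
#' reporting organ. Red bone marrow, bone surface and lymphatic nodes use
#' the dedicated estimators [rbm_dose()], [bone_surface_dose()] and
#' [lymph_node_dose()].
#'
#' @param treatment a `pd_treatment` from [run_treatment()]
#' @return a `pd_organ_doses` tibble: `organ`, `group` (main/remainder),
#'   `dose_medial_cgy`, `dose_lateral_cgy`, `dose_cgy`, `rel_err`,
#'   `n_cells`, `note`; attributes `breast_size` and `prescription_gy`
#' @export
aggregate_organ_doses <- function(treatment) {
  stopifnot(inherits(treatment, "pd_treatment"))
  plan <- attr(treatment, "plan")
  spec <- .pd_report_organs()
  cols <- c("dose_medial_cgy", "dose_lateral_cgy", "dose_cgy")
  out <- purrr::pmap(spec, function(organ, group, label) {
    row <- list(organ = organ, group = group)
    if (!is.na(label)) {
      rows <- treatment[treatment$organ == label, ]
      w <- lapply(cols, function(cl) .pd_mass_weighted(rows, cl))
      row$dose_medial_cgy <- w[[1]]$dose
      row$dose_lateral_cgy <- w[[2]]$dose
      row$dose_cgy <- w[[3]]$dose
      row$rel_err <- w[[3]]$rel_err
      row$n_cells <- w[[3]]$n_cells
      row$note <- if (w[[3]]$n_cells == 0) "all cells in primary beam" else NA
    } else {
      f <- switch(organ,
        red_bone_marrow = rbm_dose,
        bone_surface = bone_surface_dose,
        lymphatic_nodes = lymph_node_dose
      )
      d <- vapply(cols, function(cl) f(treatment, cl), numeric(1),
                  USE.NAMES = FALSE)
      row$dose_medial_cgy <- d[1]
      row$dose_lateral_cgy <- d[2]
      row$dose_cgy <- d[3]
      row$rel_err <- NA_real_
      row$n_cells <- NA_integer_
      row$note <- NA_character_
    }
    tibble::as_tibble(row)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("pd_organ_doses", class(out))
  attr(out, "breast_size") <- plan$breast_size
  attr(out, "prescription_gy") <- plan$prescription_gy
  out
}

#' @export
print.pd_organ_doses <- function(x, ...) {
  cat(
    "<pd_organ_doses> ", attr(x, "breast_size"), " breast, ",
    attr(x, "prescription_gy"), " Gy prescribed\n",
    sep = ""
  )
  NextMethod()
}

#' Bundled reference organ dose table
#'
#' The published peripheral organ doses (cGy per 50.4 Gy tumor dose) for the
#' lateral and medial tangential fields and both breast sizes, as used to
#' verify the reporting arithmetic.
#'
#' @return tibble with `organ`, `group` and per-field dose columns
#'   `lateral_small`, `lateral_large`, `medial_small`, `medial_large` (cGy)
#' @export
reference_dose_table <- function() {
  path <- system.file("extdata", "reference", "organ_doses.csv",
    package = "peridose"
  )
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Summary statistics of a pair of organ dose tables
#'
#' Given the small-breast and large-breast organ dose tables, computes the
#' headline quantities of the study: per-direction unweighted mean percent
#' increase of organ dose from the small to the large breast, dose extrema,
#' and the contralateral breast and uterus doses as percentages of the
#' prescribed dose. Doses are rounded to two decimals (cGy) and percentages
#' to one decimal, rounding halves away from zero. Because rounding is
#' applied after each arithmetic step, a total formed by summing the rounded
#' per-field columns can differ in the last digit from the rounded sum of
#' the unrounded values (e.g. a heart total of 161.41 versus 161.42 cGy);
#' the column sums are reported.
#'
#' @param small,large `pd_organ_doses` tables (or any tibble with `organ`,
#'   `dose_medial_cgy`, `dose_lateral_cgy`)
#' @param prescribed_cgy prescribed tumor dose in cGy
#' @return one-row tibble with `mean_increase_medial_pct`,
#'   `mean_increase_lateral_pct`, `min_dose_small_cgy`, `max_dose_small_cgy`,
#'   `min_dose_large_cgy`, `max_dose_large_cgy`,
#'   `breast_small_pct`, `breast_large_pct`, `uterus_small_pct`,
#'   `uterus_large_pct`
#' @export
summarize_organ_doses <- function(small, large, prescribed_cgy = 5040) {
  stopifnot(identical(small$organ, large$organ))
  pct <- function(num, den) .pd_round_half_away(100 * num / den, 1)
  inc <- function(dir) {
    mean(100 * (large[[dir]] - small[[dir]]) / small[[dir]], na.rm = TRUE)
  }
  tot_s <- small$dose_medial_cgy + small$dose_lateral_cgy
  tot_l <- large$dose_medial_cgy + large$dose_lateral_cgy
  ib <- match("breast", small$organ)
  iu <- match("uterus", small$organ)
  tibble::tibble(
    mean_increase_medial_pct = .pd_round_half_away(inc("dose_medial_cgy"), 1),
    mean_increase_lateral_pct = .pd_round_half_away(inc("dose_lateral_cgy"), 1),
    min_dose_small_cgy = .pd_round_half_away(min(tot_s, na.rm = TRUE), 2),
    max_dose_small_cgy = .pd_round_half_away(max(tot_s, na.rm = TRUE), 2),
    min_dose_large_cgy = .pd_round_half_away(min(tot_l, na.rm = TRUE), 2),
    max_dose_large_cgy = .pd_round_half_away(max(tot_l, na.rm = TRUE), 2),
    breast_small_pct = pct(tot_s[ib], prescribed_cgy),
    breast_large_pct = pct(tot_l[ib], prescribed_cgy),
    uterus_small_pct = pct(tot_s[iu], prescribed_cgy),
    uterus_large_pct = pct(tot_l[iu], prescribed_cgy)
  )
}

#' Convert the bundled reference table to per-size organ dose tables
#'
#' Reshapes [reference_dose_table()] into the two-column (medial/lateral)
#' layout produced by [aggregate_organ_doses()], for one breast size.
#'
#' @param size `"small"` or `"large"`
#' @return tibble with `organ`, `group`, `dose_medial_cgy`,
#'   `dose_lateral_cgy`, `dose_cgy`
#' @export
reference_organ_doses <- function(size = c("small", "large")) {
  size <- match.arg(size)
  ref <- reference_dose_table()
  tibble::tibble(
    organ = ref$organ,
    group = ref$group,
    dose_medial_cgy = ref[[paste0("medial_", size)]],
    dose_lateral_cgy = ref[[paste0("lateral_", size)]],
    dose_cgy = ref[[paste0("medial_", size)]] + ref[[paste0("lateral_", size)]]
  )
}
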