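# Shared, lazily built fixtures so expensive objects are constructed once
# per test run.

pd_test_env <- new.env(parent = emptyenv())

test_phantom <- function() {
  if (is.null(pd_test_env$phantom)) pd_test_env$phantom <- build_phantom()
  pd_test_env$phantom
}

test_spectra <- function() {
  if (is.null(pd_test_env$spectra)) pd_test_env$spectra <- beam_spectra()
  pd_test_env$spectra
}

test_treatment <- function() {
  if (is.null(pd_test_env$treatment)) {
    plan <- configure_tangential_fields(test_phantom())
    pd_test_env$treatment <- run_treatment(
      test_phantom(), plan,
      n_histories = 4e4, seed = 424242, spectra = test_spectra()
    )
  }
  pd_test_env$treatment
}

# a synthetic treatment table with hand-set doses, for aggregation
# arithmetic tests that need no transport
fake_treatment <- function(dose_fn, in_beam_cells = character(0)) {
  ph <- test_phantom()
  out <- tibble::tibble(
    cell = ph$label,
    organ = ph$organ,
    material = ph$material,
    mass_g = ph$mass,
    dose_medial_cgy = dose_fn(ph) / 2,
    dose_lateral_cgy = dose_fn(ph) / 2,
    dose_cgy = dose_fn(ph),
    rel_err = 0,
    primary_medial = ph$label %in% in_beam_cells,
    primary_lateral = ph$label %in% in_beam_cells,
    in_beam = ph$label %in% in_beam_cells
  )
  class(out) <- c("pd_treatment", class(out))
  attr(out, "plan") <- list(breast_size = "small", prescription_gy = 50.4)
  out
}

# slab of one material between z = 0 and z = thickness, with a thin
# downstream detector cell, inside an air world
slab_geometry <- function(material = "water", thickness = 10,
                          det_z = NULL, det_half = 0.5) {
  if (is.null(det_z)) det_z <- thickness + 5
  gb <- peridose:::.gb_new()
  peridose:::.gb_cell(gb, "slab",
    inside = list(
      peridose:::.sq_plane("x", 40), peridose:::.sq_plane("y", 40),
      peridose:::.sq_plane("z", thickness)
    ),
    outside = list(
      peridose:::.sq_plane("x", -40), peridose:::.sq_plane("y", -40),
      peridose:::.sq_plane("z", 0)
    ),
    material = material, volume = 80 * 80 * thickness, organ = "slab"
  )
  peridose:::.gb_cell(gb, "detector",
    inside = list(
      peridose:::.sq_plane("x", 40), peridose:::.sq_plane("y", 40),
      peridose:::.sq_plane("z", det_z + det_half)
    ),
    outside = list(
      peridose:::.sq_plane("x", -40), peridose:::.sq_plane("y", -40),
      peridose:::.sq_plane("z", det_z - det_half)
    ),
    material = "air", volume = 80 * 80 * 2 * det_half, organ = "detector"
  )
  peridose:::.gb_finalize(gb)
}

# first downward crossing of 50% of the plateau in a fluence edge profile
edge_position <- function(prof, plateau_below = 4) {
  f <- prof$fluence / stats::median(prof$fluence[prof$position < plateau_below])
  i <- which(f < 0.5)[1]
  stopifnot(is.finite(i), i > 1)
  prof$position[i - 1] + (0.5 - f[i - 1]) *
    (prof$position[i] - prof$position[i - 1]) / (f[i] - f[i - 1])
}

# monoenergetic pencil beam along +z starting at z0
pencil_particles <- function(n, energy, z0 = -5) {
  tibble::tibble(
    x = 0, y = 0, z = z0, ux = 0, uy = 0, uz = 1,
    energy = energy, weight = 1
  )[rep(1, n), ]
}
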