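# Tangential plan construction and treatment simulation.

test_that("plan geometry: field sizes, angles, source distances", {
  ph <- test_phantom()
  small <- configure_tangential_fields(ph, "small")
  large <- configure_tangential_fields(ph, "large")
  area <- function(p) p$field_width_cm * p$field_height_cm
  expect_equal(area(small), 160)
  expect_equal(area(large), 240)
  expect_equal(area(large) / area(small), 1.5)
  expect_equal(unname(small$gantry_deg), c(286, 115))
  expect_equal(unname(large$gantry_deg), c(301, 128))
  for (f in small$fields) {
    expect_equal(sqrt(sum((f$source - small$aim_point)^2)), 100)
    # aperture width equals the nominal field width
    expect_equal(diff(f$width_limits), 10)
    expect_equal(diff(f$height_limits), 16)
  }
  # gantry 286: source right-anterior of the patient; 115: left-posterior
  expect_lt(small$fields$medial$source[1], 0)
  expect_gt(small$fields$medial$source[2], 0)
  expect_gt(small$fields$lateral$source[1], 0)
  expect_lt(small$fields$lateral$source[2], 0)
})

test_that("posterior borders are coplanar within 1 mm at the isocenter", {
  ph <- test_phantom()
  for (size in c("small", "large")) {
    plan <- configure_tangential_fields(ph, size)
    expect_lt(border_alignment(plan), 0.1)
  }
})

test_that("the contralateral breast lies outside both apertures", {
  ph <- test_phantom()
  plan <- configure_tangential_fields(ph)
  ctr <- attr(ph, "breast_center_right")
  rb <- attr(ph, "breast_radius")
  nrm <- plan$border_normal
  # every point of the contralateral breast is on the shielded side of the
  # shared posterior border plane
  expect_gte(sum(ctr * nrm) - rb, plan$border_offset)
})

test_that("treatment normalizes the tumor to the prescription exactly", {
  tr <- test_treatment()
  i <- match("tumor", tr$cell)
  expect_equal(tr$dose_cgy[i], 5040)
  # each field contributes exactly half
  expect_equal(tr$dose_medial_cgy[i], 2520)
  expect_equal(tr$dose_lateral_cgy[i], 2520)
  expect_equal(tr$dose_cgy, tr$dose_medial_cgy + tr$dose_lateral_cgy)
})

test_that("contralateral breast sees scatter only, never primary fluence", {
  tr <- test_treatment()
  i <- match("right_breast", tr$cell)
  expect_false(tr$primary_medial[i])
  expect_false(tr$primary_lateral[i])
  expect_gt(tr$dose_cgy[i], 0)
  # the treated-side structures do see primary fluence
  expect_true(tr$in_beam[match("tumor", tr$cell)])
  expect_true(tr$in_beam[match("left_breast", tr$cell)])
})

test_that("treatment requires a seed and refuses uncertain normalization", {
  ph <- test_phantom()
  plan <- configure_tangential_fields(ph)
  expect_error(run_treatment(ph, plan, n_histories = 100), "seed")
  # with a handful of histories the tumor tally is far too noisy
  expect_error(
    run_treatment(ph, plan, n_histories = 40, seed = 5,
                  spectra = test_spectra()),
    "too uncertain|nonpositive|increase n_histories"
  )
})

test_that("doses are linear in the prescription", {
  ph <- test_phantom()
  tr1 <- test_treatment()
  plan2 <- configure_tangential_fields(ph)
  plan2$prescription_gy <- 2 * 50.4
  tr2 <- run_treatment(ph, plan2, n_histories = 4e4, seed = 424242,
                       spectra = test_spectra())
  expect_equal(tr2$dose_cgy, 2 * tr1$dose_cgy)
})

test_that("the verification chain reads out six ordered positions", {
  tv <- run_tld_verification(test_treatment())
  expect_equal(nrow(tv), 6)
  expect_equal(tv$distance_cm, seq(15, 40, by = 5))
  fix <- generate_tld_fixture(tv, relative_sd = 0.04, seed = 9)
  cmp <- run_tld_verification(test_treatment(), reference = fix)
  expect_true(all(c("reference_cgy", "percent_diff") %in% names(cmp)))
  expect_true(is.finite(attr(cmp, "mean_abs_percent_diff")))
})
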