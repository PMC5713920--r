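# Humanoid phantom construction: masses, volumes, helper tables.

test_that("total phantom mass matches the reference adult within 2%", {
  ph <- test_phantom()
  mass_kg <- sum(ph$mass[ph$label != "world"]) / 1000
  expect_equal(mass_kg, 73.54, tolerance = 0.02)
})

test_that("breast volume is honored within 0.5% for both sizes", {
  ph <- test_phantom()
  v_small <- sum(ph$volume[ph$label %in% c("left_breast", "tumor")])
  expect_equal(v_small, 168.5, tolerance = 0.005)
  ph_l <- build_phantom(1354.4)
  v_large <- sum(ph_l$volume[ph_l$label %in% c("left_breast", "tumor")])
  expect_equal(v_large, 1354.4, tolerance = 0.005)
  # larger breast, larger radius
  expect_gt(attr(ph_l, "breast_radius"), attr(ph, "breast_radius"))
})

test_that("tumor site is a 0.5 cm sphere at the breast center", {
  ph <- test_phantom()
  i <- match("tumor", ph$label)
  expect_equal(ph$volume[i], 4 / 3 * pi * 0.5^3, tolerance = 1e-6)
  expect_equal(ph$organ[i], "tumor")
})

test_that("cell masses are volume times material density", {
  ph <- test_phantom()
  lib <- pd_material_library()
  dens <- lib$density[match(ph$material, lib$material)]
  expect_equal(ph$mass, ph$volume * dens, ignore_attr = TRUE)
})

test_that("organ labelling separates laterality and treated structures", {
  ph <- test_phantom()
  expect_setequal(ph$label[ph$organ == "breast"], "right_breast")
  expect_setequal(ph$label[ph$organ == "lung"], "right_lung")
  expect_true("lung_left" %in% ph$organ)
  expect_true("chest_wall" %in% ph$organ)
  expect_true("skin_trunk" %in% ph$organ)
  # six verification spheres
  expect_equal(sum(ph$organ == "tld"), 6)
})

test_that("marrow site fractions and lymph cluster weights are normalized", {
  sites <- rbm_site_table()
  expect_equal(sum(sites$fraction), 1, tolerance = 1e-6)
  expect_true(all(sites$bone_organ %in% test_phantom()$organ))
  cl <- lymph_cluster_table()
  expect_equal(sum(cl$weight), 100)
  expect_equal(nrow(cl), 8)
})

test_that("the large-breast phantom is also disjoint and gap-free", {
  ph_l <- build_phantom(1354.4)
  a <- audit_geometry(ph_l, n = 5e4, seed = 7)
  expect_identical(a$n_double, 0L)
  expect_identical(a$n_orphan, 0L)
})
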