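# Constructive-solid-geometry kernel: location, ray tracing, audits.

test_that("locate resolves cells, exclusions and the exterior", {
  geom <- slab_geometry("water", thickness = 10)
  lab <- locate(geom, rbind(
    c(0, 0, 5), # slab
    c(0, 0, 15), # detector
    c(0, 0, 200), # world air
    c(0, 0, 400) # outside the world sphere
  ))
  expect_equal(lab, c("slab", "detector", "world", "exterior"))
})

test_that("phantom exclusions carve embedded cells out of their host", {
  ph <- test_phantom()
  tc <- attr(ph, "tumor_center")
  expect_equal(locate(ph, rbind(tc)), "tumor")
  # just outside the tumor sphere but inside the breast
  expect_equal(locate(ph, rbind(tc + c(0, 0, 0.6))), "left_breast")
  # verification spheres carved out of the liver
  expect_equal(locate(ph, rbind(c(-4, 0, 37))), "tld_1")
})

test_that("ray tracing telescopes exactly through the geometry", {
  geom <- slab_geometry("water", thickness = 10)
  tr <- trace_ray(geom, origin = c(0, 0, -20), direction = c(0, 0, 1))
  expect_true(all(diff(tr$t0) > 0))
  # segments are contiguous: each ends where the next begins
  expect_equal(tr$t1[-nrow(tr)], tr$t0[-1], tolerance = 1e-9)
  expect_equal(tr$length, tr$t1 - tr$t0)
  # slab crossing has the slab thickness
  expect_equal(tr$length[tr$cell == "slab"], 10, tolerance = 1e-9)
  expect_equal(tr$length[tr$cell == "detector"], 1, tolerance = 1e-9)
})

test_that("oblique crossings have the secant-scaled path length", {
  geom <- slab_geometry("water", thickness = 10)
  d <- c(0.6, 0, 0.8)
  tr <- trace_ray(geom, origin = c(0, 0, -20), direction = d)
  expect_equal(tr$length[tr$cell == "slab"], 10 / 0.8, tolerance = 1e-9)
})

test_that("surfaces are deduplicated across cells", {
  geom <- slab_geometry("water", thickness = 10)
  # 4 lateral planes shared by slab and detector + 4 z planes + world sphere
  expect_equal(nrow(geom$surfaces), 9)
})

test_that("the phantom geometry is disjoint and gap-free", {
  a <- audit_geometry(test_phantom(), n = 5e4, seed = 99)
  expect_identical(a$n_double, 0L)
  expect_identical(a$n_orphan, 0L)
})

test_that("the water tank geometries are disjoint and gap-free", {
  for (kind in c("pdd", "profile")) {
    g <- build_water_phantom(kind)
    a <- audit_geometry(g,
      n = 2e4, lower = c(-26, -26, -2), upper = c(26, 26, 51), seed = 3
    )
    expect_identical(a$n_double, 0L)
    expect_identical(a$n_orphan, 0L)
  }
})
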