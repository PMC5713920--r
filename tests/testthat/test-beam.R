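# Treatment-head model: filter design, spectra bookkeeping, field geometry.

test_that("flattening filter thickness decreases with radius", {
  flt <- design_flattening_filter(n_radii = 9)
  expect_true(all(diff(flt$thickness_cm) < 0))
  expect_true(all(flt$thickness_cm > 0))
})

test_that("head simulation is deterministic and conserves bookkeeping", {
  flt <- design_flattening_filter(n_radii = 9)
  s1 <- simulate_head(2e4, seed = 31, filter = flt)
  s2 <- simulate_head(2e4, seed = 31, filter = flt)
  expect_equal(s1, s2)
  expect_true(all(s1$weight >= 0))
  # ring/bin edges are an exact lattice
  expect_equal(s1$r_hi - s1$r_lo, rep(0.2, nrow(s1)))
  expect_equal(s1$e_hi - s1$e_lo, rep(0.25, nrow(s1)))
  expect_true(all(s1$e_hi <= 8 + 1e-9))
})

test_that("bundled spectra soften from the center outwards", {
  sp <- test_spectra()
  by_ring <- beam_mean_energy(sp, by_ring = TRUE)
  expect_true(all(diff(by_ring$mean_energy_mev) <= 0))
  em <- beam_mean_energy(sp)
  expect_gt(em, 1)
  expect_lt(em, 3)
})

test_that("emitted photons have unit directions and leakage weights", {
  sp <- test_spectra()
  fld <- beam_field(
    source = c(0, 0, -100), target = c(0, 0, 0),
    width_limits = c(-5, 5), height_limits = c(-5, 5)
  )
  set.seed(5)
  ph <- emit_beam(fld, 2e4, sp)
  expect_equal(ph$ux^2 + ph$uy^2 + ph$uz^2, rep(1, nrow(ph)), tolerance = 1e-9)
  expect_true(all(ph$weight[ph$in_field] == 1))
  expect_true(all(ph$weight[!ph$in_field] < 0.01)) # heavy jaw attenuation
  expect_true(all(ph$energy > 0 & ph$energy <= 8))
})

test_that("the field edge is within 2 mm of nominal", {
  sp <- test_spectra()
  fld <- beam_field(
    source = c(0, 0, -100), target = c(0, 0, 0),
    width_limits = c(-5, 5), height_limits = c(-5, 5)
  )
  set.seed(6)
  prof <- field_edge_profile(fld, positions = seq(3, 7, by = 0.1), n = 2e5,
                             spectra = sp)
  # 50%-of-plateau crossing position
  expect_lt(abs(edge_position(prof) - 5), 0.2)
})

test_that("asymmetric apertures shift the edge accordingly", {
  sp <- test_spectra()
  fld <- beam_field(
    source = c(0, 0, -100), target = c(0, 0, 0),
    width_limits = c(-2, 8), height_limits = c(-8, 8)
  )
  set.seed(7)
  ph <- emit_beam(fld, 5e4, sp)
  a1 <- 100 * (ph$ux * fld$width_dir[1] + ph$uy * fld$width_dir[2] +
    ph$uz * fld$width_dir[3]) /
    (ph$ux * fld$axis[1] + ph$uy * fld$axis[2] + ph$uz * fld$axis[3])
  expect_true(all(a1[ph$in_field] >= -2 - 1e-9))
  expect_true(all(a1[ph$in_field] <= 8 + 1e-9))
})

test_that("spectra round-trip through the TSV serialization", {
  sp <- test_spectra()
  path <- tempfile(fileext = ".tsv")
  write_beam_spectra(sp, path)
  sp2 <- read_beam_spectra(path)
  expect_equal(as.data.frame(sp2), as.data.frame(sp), tolerance = 1e-12)
  unlink(path)
})
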