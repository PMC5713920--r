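# Interaction-coefficient tables against published reference values.

test_that("water attenuation coefficients match reference values", {
  w <- material("water")
  # NIST XCOM water mass attenuation (without coherent) and muen, cm^2/g
  expect_equal(get_coefficients(w, 1.25)$total, 0.06323, tolerance = 0.01)
  expect_equal(get_coefficients(w, 1.25)$muen, 0.02965, tolerance = 0.02)
  expect_equal(get_coefficients(w, 0.1)$total, 0.1707, tolerance = 0.02)
  expect_equal(get_coefficients(w, 6)$total, 0.0277, tolerance = 0.02)
})

test_that("per-process coefficients sum to the total", {
  for (m in c("water", "soft_tissue", "bone", "lung", "air")) {
    tab <- get_coefficients(material(m), c(0.05, 0.5, 2, 6))
    expect_equal(tab$total, tab$pe + tab$incoherent + tab$pair)
    expect_true(all(tab$muen <= tab$total))
    expect_true(all(tab$muen > 0))
  }
})

test_that("tissue-to-bone absorption ratio is near unity at megavoltage", {
  expect_equal(muen_ratio("soft_tissue", "bone", 2), 1.063, tolerance = 0.01)
  # ratio accepts material objects too
  expect_equal(
    muen_ratio(material("soft_tissue"), material("bone"), 2),
    muen_ratio("soft_tissue", "bone", 2)
  )
})

test_that("material construction is validated", {
  expect_error(material("unobtainium"), "unknown material")
  expect_error(
    material("x", density = 1, composition = c(H = 0.5, O = 0.4)),
    "sum to 1"
  )
  m <- material("mix", density = 1.2, composition = c(H = 0.1, O = 0.9))
  expect_s3_class(m, "pd_material")
  expect_equal(m$density, 1.2)
})

test_that("coefficient lookup rejects energies outside the tabulated range", {
  w <- material("water")
  expect_error(get_coefficients(w, 0.001), "out of tabulated range")
  expect_error(get_coefficients(w, 9), "out of tabulated range")
})

test_that("Klein-Nishina total cross-section has the right limits", {
  # long-wavelength limit approaches the Thomson cross-section
  thomson <- 6.6524587e-25
  expect_equal(kn_total_cs(1e-4), thomson, tolerance = 1e-3)
  # decreasing with energy
  e <- c(0.1, 0.5, 1, 2, 6)
  expect_true(all(diff(kn_total_cs(e)) < 0))
  # transfer cross-section bounded by the total
  expect_true(all(kn_transfer_cs(e) < kn_total_cs(e)))
})
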