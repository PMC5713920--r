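# Synthetic measurement fixtures: determinism, noiseless exactness, noise
# statistics.

test_that("fixtures are bit-identical under a fixed seed", {
  a <- generate_reference_pdd(seed = 12)
  b <- generate_reference_pdd(seed = 12)
  expect_identical(a, b)
  c1 <- generate_reference_profile(seed = 12)
  c2 <- generate_reference_profile(seed = 12)
  expect_identical(c1, c2)
  d1 <- generate_tld_fixture(c(4, 2, 1, 0.5, 0.2, 0.1), seed = 12)
  d2 <- generate_tld_fixture(c(4, 2, 1, 0.5, 0.2, 0.1), seed = 12)
  expect_identical(d1, d2)
  # different seeds differ
  expect_false(identical(a$dose, generate_reference_pdd(seed = 13)$dose))
})

test_that("noiseless depth-dose model peaks at the closed-form dmax", {
  p <- generate_reference_pdd(
    depths = seq(0.05, 30, by = 0.05), noise_sd = 0, seed = 1
  )
  alpha <- attr(p, "alpha")
  beta <- attr(p, "beta")
  # analytic maximum of (1-exp(-a d)) exp(-b d)
  dmax <- log((alpha + beta) / beta) / alpha
  expect_equal(p$depth_cm[which.max(p$dose)], dmax, tolerance = 0.05)
  expect_equal(dmax, 1.5, tolerance = 1e-9)
  # the target falloff ratio
  ratio <- p$dose[which.min(abs(p$depth_cm - 10))] / max(p$dose)
  expect_equal(ratio, 0.65, tolerance = 0.01)
  expect_equal(max(p$dose), 1, tolerance = 1e-4)
})

test_that("noiseless profile crosses 50% at the nominal half-width", {
  pr <- generate_reference_profile(
    field_size = 10, depth = 10,
    offsets = seq(-9, 9, by = 0.01), noise_sd = 0, seed = 1
  )
  hw <- attr(pr, "half_width_cm")
  expect_equal(hw, 5.5)
  # penumbra only, reversed so dose is strictly increasing for approx()
  sel <- pr$position_cm > 4 & pr$position_cm < 7
  cross <- stats::approx(
    rev(pr$dose[sel]), rev(pr$position_cm[sel]), xout = 0.5
  )$y
  expect_equal(cross, hw, tolerance = 1e-3)
  # plateau flat, symmetric
  plateau <- pr$dose[abs(pr$position_cm) < 3]
  expect_lt(max(plateau) - min(plateau), 1e-6)
  expect_equal(pr$dose, rev(pr$dose), tolerance = 1e-12)
})

test_that("widening the field moves the DTA result by the same distance", {
  off <- seq(0, 9, by = 0.01)
  a <- generate_reference_profile(field_size = 10, offsets = off,
                                  noise_sd = 0, seed = 1)
  b <- generate_reference_profile(field_size = 10.4, offsets = off,
                                  noise_sd = 0, seed = 1)
  d <- dta(a$position_cm, a$dose, b$position_cm, b$dose)
  # half-width grows by 0.2 cm at the surface, 0.22 cm at 10 cm depth
  expect_equal(attr(d, "max_dta_cm"), 0.22, tolerance = 0.01)
})

test_that("noise statistics behave like the configured lognormal", {
  doses <- rep(10, 6)
  z <- generate_tld_fixture(doses, relative_sd = 0, seed = 3)
  expect_equal(z$dose_cgy, doses)
  f <- generate_tld_fixture(rep(10, 2000), relative_sd = 0.04, seed = 3,
                            distances = seq_len(2000))
  dev <- f$dose_cgy / 10 - 1
  # folded-normal mean |x| ~ sd sqrt(2/pi) ~ 3.2%
  expect_equal(mean(abs(dev)), 0.04 * sqrt(2 / pi), tolerance = 0.15)
  expect_equal(mean(dev), 0, tolerance = 0.005)
})

test_that("fixture preconditions are enforced", {
  expect_error(generate_reference_pdd(seed = 1, noise_sd = 0.2))
  expect_error(generate_reference_profile(seed = 1, noise_sd = -0.01))
  expect_error(generate_tld_fixture(1:6, relative_sd = 0.5, seed = 1))
  expect_error(generate_reference_pdd(noise_sd = 0.01), "seed")
})
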