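# Water-tank curves and the distance-to-agreement metric.

test_that("dta is zero for a curve compared with itself", {
  x <- seq(0, 10, by = 0.5)
  v <- exp(-x / 3)
  d <- dta(x, v, x, v)
  expect_true(all(d$dta_cm < 1e-9))
  expect_lt(attr(d, "max_dta_cm"), 1e-9)
})

test_that("dta of a shifted ramp equals the shift", {
  x <- seq(0, 10, by = 0.1)
  v <- pmax(0, pmin(1, (10 - x) / 5))
  d <- dta(x, v, x + 0.3, v)
  sel <- is.finite(d$dta_cm)
  expect_equal(max(d$dta_cm[sel]), 0.3, tolerance = 1e-6)
})

test_that("dta only evaluates the requested gradient region", {
  x <- seq(0, 10, by = 0.1)
  v <- pmax(0, pmin(1, (10 - x) / 5))
  d <- dta(x, v, x, v, region = c(0.2, 0.8))
  expect_true(all(d$value >= 0.2 & d$value <= 0.8))
})

test_that("pdd has a buildup maximum and megavoltage falloff", {
  p <- compute_pdd(n_histories = 5e4, seed = 301, spectra = test_spectra())
  expect_gte(attr(p, "dmax_cm"), 1)
  expect_lte(attr(p, "dmax_cm"), 2)
  expect_gt(attr(p, "pdd10"), 55)
  expect_lt(attr(p, "pdd10"), 80)
  # beyond buildup, dose decreases overall (linear trend on the tail)
  tail <- p[p$depth_cm >= 3, ]
  expect_lt(stats::coef(stats::lm(pdd ~ depth_cm, tail))[2], 0)
  expect_equal(max(p$pdd), 100)
})

test_that("profile is flat in-field, symmetric, and low out-of-field", {
  pr <- compute_profile(n_histories = 2e5, seed = 311,
                        spectra = test_spectra())
  ctr <- pr$dose[abs(pr$position_cm) <= 3]
  expect_lt(stats::sd(ctr) / mean(ctr), 0.15)
  out <- pr$dose[abs(pr$position_cm) >= 8.25]
  expect_true(all(out < 0.1))
  # symmetry within statistics
  left <- pr$dose[match(-pr$position_cm, pr$position_cm)]
  expect_lt(stats::median(abs(pr$dose - left)), 0.1)
})

test_that("curve objects carry tidy summaries and plots", {
  p <- generate_reference_pdd(seed = 2, noise_sd = 0)
  g <- glance(p)
  expect_equal(g$dmax_cm, 1.5)
  expect_s3_class(autoplot(p), "ggplot")
  pr <- generate_reference_profile(seed = 2, noise_sd = 0)
  expect_s3_class(autoplot(pr), "ggplot")
})
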