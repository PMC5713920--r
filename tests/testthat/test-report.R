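# Organ dose aggregation, marrow/lymph estimators and summary arithmetic.

test_that("the packaged reference table reproduces the published summary", {
  s <- reference_organ_doses("small")
  l <- reference_organ_doses("large")
  sm <- summarize_organ_doses(s, l)
  expect_equal(sm$mean_increase_lateral_pct, 85.2)
  expect_equal(sm$mean_increase_medial_pct, 67.4)
  expect_equal(sm$min_dose_small_cgy, 2.32)
  expect_equal(sm$min_dose_large_cgy, 4.06)
  expect_equal(sm$max_dose_large_cgy, 141.59)
  expect_equal(sm$breast_small_pct, 1.4)
  expect_equal(sm$breast_large_pct, 1.6)
  expect_equal(sm$uterus_small_pct, 0.1)
  expect_equal(sm$uterus_large_pct, 0.1)
  # minima are the urinary bladder, maxima the thymus
  tot_s <- s$dose_medial_cgy + s$dose_lateral_cgy
  tot_l <- l$dose_medial_cgy + l$dose_lateral_cgy
  expect_equal(s$organ[which.min(tot_s)], "urinary_bladder")
  expect_equal(l$organ[which.max(tot_l)], "thymus")
  # contralateral breast large-plan total
  expect_equal(tot_l[match("breast", l$organ)], 83.10)
  # heart small-plan total above 1.6 Gy (column sums give 161.42)
  expect_gte(tot_s[match("heart", s$organ)], 160)
  expect_equal(tot_s[match("heart", s$organ)], 161.42)
})

test_that("identical tables give zero percent increase", {
  s <- reference_organ_doses("small")
  sm <- summarize_organ_doses(s, s)
  expect_equal(sm$mean_increase_lateral_pct, 0)
  expect_equal(sm$mean_increase_medial_pct, 0)
})

test_that("summarize validates organ alignment", {
  s <- reference_organ_doses("small")
  l <- reference_organ_doses("large")
  expect_error(summarize_organ_doses(s, l[27:1, ]))
})

test_that("rounding is half away from zero", {
  r <- peridose:::.pd_round_half_away
  expect_equal(r(0.125, 2), 0.13)
  expect_equal(r(-0.125, 2), -0.13)
  expect_equal(r(2.5, 0), 3)
  expect_equal(r(-2.5, 0), -3)
  expect_equal(r(1.05, 1), 1.1)
})

test_that("aggregation covers 27 organs and is linear in dose", {
  tr1 <- fake_treatment(function(ph) ph$volume * 0 + 2)
  od1 <- aggregate_organ_doses(tr1)
  expect_equal(nrow(od1), 27)
  expect_equal(sum(od1$group == "main"), 14)
  expect_equal(sum(od1$group == "remainder"), 13)
  tr3 <- fake_treatment(function(ph) ph$volume * 0 + 6)
  od3 <- aggregate_organ_doses(tr3)
  expect_equal(od3$dose_cgy, 3 * od1$dose_cgy)
  expect_equal(od3$dose_medial_cgy, 3 * od1$dose_medial_cgy)
})

test_that("uniform cell doses aggregate to the same organ dose", {
  tr <- fake_treatment(function(ph) rep(5, length(ph$label)))
  od <- aggregate_organ_doses(tr)
  # every mass-weighted mean of a constant is that constant; the marrow
  # entry additionally carries the tissue-to-bone conversion factor
  direct <- od$dose_cgy[od$organ != "red_bone_marrow"]
  expect_equal(direct, rep(5, 26), tolerance = 1e-9)
  ratio <- muen_ratio("soft_tissue", "bone", beam_mean_energy(beam_spectra()))
  expect_equal(od$dose_cgy[od$organ == "red_bone_marrow"], 5 * ratio)
})

test_that("in-beam cells are excluded; fully exposed organs become NA", {
  base <- function(ph) rep(1, length(ph$label))
  # flag the whole brain as in-beam: its report entry must be NA with a
  # note, never a silent zero
  tr <- fake_treatment(base, in_beam_cells = "brain")
  od <- aggregate_organ_doses(tr)
  i <- match("brain", od$organ)
  expect_true(is.na(od$dose_cgy[i]))
  expect_match(od$note[i], "primary beam")
  # partially exposed organs keep their unexposed cells: flag one kidney
  tr2 <- fake_treatment(function(ph) {
    d <- rep(1, length(ph$label))
    d[ph$label == "kidney_l"] <- 100
    d
  }, in_beam_cells = "kidney_l")
  od2 <- aggregate_organ_doses(tr2)
  expect_equal(od2$dose_cgy[match("kidneys", od2$organ)], 1)
})

test_that("the reported lung is the contralateral (right) lung", {
  tr <- fake_treatment(function(ph) {
    d <- rep(1, length(ph$label))
    d[ph$label == "left_lung"] <- 1000
    d
  })
  od <- aggregate_organ_doses(tr)
  expect_equal(od$dose_cgy[match("lung", od$organ)], 1)
})

test_that("marrow dose follows the site-weighted formula excluding ribs", {
  # rib dose must not influence the marrow estimate
  tr <- fake_treatment(function(ph) {
    d <- rep(0, length(ph$label))
    d[ph$organ == "bone_spine"] <- 10
    d[ph$organ == "bone_ribs"] <- 1e6
    d
  })
  sites <- rbm_site_table()
  keep <- !sites$site %in% c("ribcage", "shoulder_girdle")
  f <- sites$fraction[keep] / sum(sites$fraction[keep])
  ratio <- muen_ratio("soft_tissue", "bone", beam_mean_energy(beam_spectra()))
  expected <- sum(f[sites$site[keep] == "spine"]) * 10 * ratio
  expect_equal(rbm_dose(tr), expected, tolerance = 1e-9)
  # bone surface likewise excludes the ribs
  expect_lt(bone_surface_dose(tr), 11)
})

test_that("lymph node estimator applies the cluster weights", {
  # all clusters at the same dose return that dose
  tr <- fake_treatment(function(ph) rep(7, length(ph$label)))
  expect_equal(lymph_node_dose(tr), 7, tolerance = 1e-9)
  # only the 41.1% small-intestine cluster nonzero at 10 -> 4.11
  tr2 <- fake_treatment(function(ph) {
    d <- rep(0, length(ph$label))
    d[ph$organ == "small_intestine"] <- 10
    d
  })
  expect_equal(lymph_node_dose(tr2), 4.11, tolerance = 1e-9)
})

test_that("surrogate entries equal their source-cell doses", {
  tr <- fake_treatment(function(ph) seq_along(ph$label))
  od <- aggregate_organ_doses(tr)
  # extra-thoracic tissue = neck soft-tissue cell
  neck <- peridose:::.pd_mass_weighted(
    tr[tr$organ == "et_tissue", ], "dose_cgy"
  )$dose
  expect_equal(od$dose_cgy[match("extra_thoracic_tissue", od$organ)], neck)
  # bone surface = mass-weighted non-rib bone
  expect_equal(
    od$dose_cgy[match("bone_surface", od$organ)],
    bone_surface_dose(tr)
  )
  # oral mucosa reported from its dedicated cell
  expect_equal(
    od$dose_cgy[match("oral_mucosa", od$organ)],
    tr$dose_cgy[match("oral_mucosa", tr$cell)]
  )
})

test_that("a real treatment aggregates with tumor structures excluded", {
  od <- aggregate_organ_doses(test_treatment())
  expect_equal(nrow(od), 27)
  expect_false("tumor" %in% od$organ)
  expect_false(any(is.na(od$dose_cgy[match(c("breast", "heart"), od$organ)])))
  expect_s3_class(autoplot(od), "ggplot")
})
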