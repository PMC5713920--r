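# peridose

Monte Carlo estimation of out-of-field (peripheral) organ doses from
tangential 6 MV breast radiotherapy, as an R package.

## The scientific problem

A tangential-pair breast treatment delivers a prescribed 50.4 Gy to the
treated breast through two opposed oblique fields. Photons scattered in
the patient and leaking through the collimator also reach every other
organ. Those peripheral doses are small — tenths of a percent to a few
percent of the prescription — but they are delivered to healthy tissue
across the whole body and drive the risk of radiation-induced second
cancers, so estimating them per organ matters clinically. They are hard
to measure in vivo and below the validity range of most treatment
planning systems, which makes Monte Carlo transport in a whole-body
phantom the reference method.

`peridose` implements the full pipeline at desk scale:

* **materials_physics** — bundled photon interaction tables
  (photoelectric, incoherent, pair production, mass energy-absorption)
  for water, soft tissue, bone, lung, air, and tungsten, with log-log
  interpolation and analog interaction sampling.
* **beam_model** — a two-step 6 MV linac model: a treatment-head
  simulation through a parametric tungsten flattening filter produces
  radially resolved annular spectra (0.2 cm rings, 0.25 MeV bins);
  a point source re-emits photons through a rectangular aperture with
  attenuated, flagged collimator leakage.
* **phantom_geometry** — a MIRD-style quadric CSG humanoid phantom
  (69 cells) with parameterized breast volume, a raised left arm, a
  tumor cell in the left breast, and six midline TLD cells; plus a
  Monte Carlo geometry auditor.
* **transport_tally** — an analog photon transport engine (C++ via
  Rcpp) scoring track-length fluence, uncollided in-field ("primary")
  fluence, and collision kerma per cell, with 20-batch relative errors
  and an exact energy-balance check.
* **treatment_sim** — opposed tangential pairs (286°/115°, 10 × 16 cm
  for a ~260 cm³ breast; 301°/128°, 12 × 20 cm for ~1350 cm³) with
  exactly coplanar posterior borders and per-field normalization to
  half the prescription at the tumor.
* **organ_dose_report** — 27-organ mass-weighted dose table with
  in-beam exclusion rules, a site-weighted red-bone-marrow formula,
  bone-surface and lymph-node models, and derived summary statistics
  checked against a bundled reference table.
* **synthetic_data** — closed-form seeded fixtures (depth-dose curve,
  lateral profile, TLD readings with 4% noise) so every verification
  stage runs with no external data.

## Worked example

```r
library(peridose)

phantom <- build_phantom()        # small-breast phantom, ~74.8 kg
spectra <- beam_spectra()         # bundled annular spectra, mean 2.05 MeV

plan <- configure_tangential_fields(phantom, breast_size = "small")
border_alignment(plan)            # 7.1e-15 cm: posterior borders coplanar

treatment <- run_treatment(phantom, plan, n_histories = 1e6,
                           seed = 1, spectra = spectra)
organ_doses <- aggregate_organ_doses(treatment)
```

Representative numbers from this exact run (seed 1, 10⁶ histories per
field, doses in cGy for the full 5040 cGy course):

| organ            | medial | lateral | total |
|------------------|-------:|--------:|------:|
| breast (contralateral) | 7.82 | 20.82 | 28.64 |
| lung (contralateral)   | 2.23 |  9.41 | 11.64 |
| heart            |  5.17 |  10.75 | 15.92 |
| stomach          |  1.34 |   1.50 |  2.83 |
| thyroid          |  0.21 |   0.72 |  0.93 |
| urinary bladder  |  0.10 |   0.01 |  0.11 |
| red bone marrow  |  0.15 |   0.24 |  0.39 |

The tumor cell receives exactly 5040 cGy by construction (each field is
normalized to 2520 cGy there). The contralateral breast gets 0.57% of
the prescription and sees **zero primary fluence** — only scatter and
collimator leakage — and midline organ doses fall monotonically with
distance below the field border (stomach 2.83 → small intestine 0.38 →
bladder 0.11 cGy). Engine water-tank curves agree with the closed-form
reference curves to within 2 mm distance-to-agreement in the penumbra
and build-up regions, and the six midline TLD cells reproduce a 4%-noise
synthetic measurement set with a 3.1% mean absolute difference.

Summary statistics against the bundled reference table:

```r
summarize_organ_doses(reference_organ_doses("small"),
                      reference_organ_doses("large"))
#> mean increase (large vs small): medial +67.4%, lateral +85.2%
#> minimum organ dose: 2.32 cGy (small), 4.06 cGy (large), both bladder
#> contralateral breast: 1.4% / 1.6% of prescription
```

## Documentation

See the methods vignette (`vignettes/peridose-methods.Rmd`) for the
physics and modelling details, and the help pages (`?run_treatment`,
`?aggregate_organ_doses`, `?build_phantom`, `?run_transport`) for the
interfaces.
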