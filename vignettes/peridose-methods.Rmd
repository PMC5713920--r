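---
title: "Methods: Monte Carlo out-of-field dosimetry with peridose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo out-of-field dosimetry with peridose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
# Chunks are not evaluated at build time: the full study below runs
# several minutes of Monte Carlo transport.
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

```{r}
library(peridose)
```

## Scientific problem

Tangential-pair breast irradiation delivers a prescribed dose (here
50.4 Gy, split equally between a medial and a lateral field) to the
treated breast, but photons scattered in the patient and in the
treatment head also deposit small doses in every other organ. These
peripheral doses — fractions of a percent to a few percent of the
prescription — drive the risk of radiation-induced second cancers and
are difficult to measure in vivo. `peridose` estimates them with an
analog Monte Carlo photon transport calculation in a whole-body
humanoid phantom, and reports per-organ doses with Monte Carlo
uncertainties.

## Materials and photon physics

Interaction data live in `inst/extdata/xs` as energy-indexed tables of
photoelectric, incoherent (Compton), and pair-production mass
attenuation coefficients plus mass energy-absorption coefficients,
for water, soft tissue, bone, lung, air, and tungsten. Tables were
precomputed (see `data-raw/`) from elemental mixture rules on standard
compositions; `get_coefficients()` interpolates them log-log.

```{r}
m <- material("soft_tissue")
get_coefficients(m, energy = 2)         # cm^2/g at 2 MeV
muen_ratio("soft_tissue", "bone", 2)    # mass energy-absorption ratio
```

Transport is analog (no variance reduction): photons undergo
photoelectric absorption, Klein–Nishina incoherent scattering, and
pair production; secondaries below a 10 keV cutoff deposit locally.
Charged-particle equilibrium is assumed, so collision kerma scored
from track-length fluence approximates absorbed dose — a good
approximation everywhere outside the first few millimetres of
build-up, and conservative out of field where the photon fluence is
soft and diffuse.

## Two-step beam model

The 6 MV treatment head is modelled once, independent of the patient:

1. `simulate_head()` transports bremsstrahlung-like source photons
   through a cone-stacked tungsten flattening filter
   (`design_flattening_filter()`) and scores an annular phase space:
   photon weight per 0.2 cm radial ring (at 100 cm) per 0.25 MeV
   energy bin. The bundled result is returned by `beam_spectra()`.
2. `emit_beam()` re-emits photons from a point source through a
   rectangular aperture using those ring-resolved spectra, so the
   beam softens off axis as a flattening-filtered beam does. Photons
   aimed outside the aperture are kept with a heavily attenuated
   weight (collimator leakage) and flagged so they never contribute
   to "primary" (uncollided, in-field) fluence tallies.

```{r}
spectra <- beam_spectra()
beam_mean_energy(spectra)                   # ~MeV, fluence-weighted
beam_mean_energy(spectra, by_ring = TRUE)   # softening with radius
```

## Phantom

`build_phantom()` constructs a gender-neutral MIRD-style adult phantom
from quadric constructive solid geometry: elliptical-cylinder trunk
with lungs, heart, ribs, spine, abdominal and pelvic organs, head and
neck with thyroid and salivary glands, legs, a raised left arm
(cleared from the tangential beams), two hemispherical breasts with a
parameterized volume, a 0.5 cm radius tumor cell in the left breast,
and six point-like TLD cells down the phantom midline at 15–40 cm
from the field border. `audit_geometry()` Monte Carlo samples the
geometry to verify cells are disjoint and volumes match their
analytic values.

```{r}
phantom <- build_phantom()           # ~260 cm^3 breasts ("small")
large <- build_phantom(breast_volume = 1354.4)
audit_geometry(phantom)
```

## Transport and tallies

`run_transport()` moves particles through the geometry with a
first-match cell locator and surface-to-surface ray tracing, scoring
per-cell track-length fluence, primary (uncollided, in-field) fluence,
and collision kerma. Histories are split into 20 batches; reported
relative errors are batch standard errors of the mean.
`energy_balance()` checks that source energy equals deposited plus
cutoff plus escaped energy to round-off.

## Treatment simulation

`configure_tangential_fields()` builds the opposed tangential pair:
gantry angles 286°/115° with a 10 × 16 cm aperture for the small
breast, 301°/128° with 12 × 20 cm for the large breast. The two
posterior field borders are made exactly coplanar — the classic
non-divergent matched border — by placing both borders in the single
plane through the two source positions that clears the contralateral
breast; `border_alignment()` verifies coplanarity numerically. Each
field is then normalized independently so the tumor cell receives
half the prescription:

```{r}
plan <- configure_tangential_fields(phantom, breast_size = "small")
treatment <- run_treatment(phantom, plan,
                           n_histories = 1e6, seed = 20130613,
                           spectra = spectra)
treatment      # per-cell doses in cGy with relative errors
glance(treatment)
```

With this construction the primary beam intersects only the treated
breast, tumor, chest wall, and overlying skin; every other cell sees
scatter and leakage only, which the engine confirms via the primary
fluence tally.

## Organ-dose reporting

`aggregate_organ_doses()` converts cell doses into a 27-organ report
(14 main organs, 13 remainder organs):

* Organ doses are mass-weighted means over the organ's cells,
  **excluding** any cell touched by the primary beam — the report is
  about out-of-field dose. If every cell of an organ is in-beam the
  organ is reported as `NA` with a note, never as zero.
* Red bone marrow uses a site-weighted formula: site fractions from
  `rbm_site_table()` minus sites shielded by in-beam structures
  (ribcage, shoulder girdle), renormalized, times the
  soft-tissue-to-bone mass energy-absorption ratio at the beam mean
  energy (`rbm_dose()`).
* Bone surface is approximated by non-rib bone dose
  (`bone_surface_dose()`); lymphatic nodes are a weighted mean over
  anatomical clusters with `lymph_cluster_table()` weights summing
  to 100% (`lymph_node_dose()`).
* Doses are rounded half-away-from-zero to 0.01 cGy and percentages
  to 0.1%.

`summarize_organ_doses()` derives the headline statistics for a
small-versus-large breast comparison (mean percentage increase per
field, extreme organ doses, contralateral-breast and uterus
percentages), and `reference_organ_doses()` returns a bundled
reference table against which the package's own arithmetic is tested.

```{r}
organ_doses <- aggregate_organ_doses(treatment)
organ_doses
autoplot(organ_doses)
```

## Verification fixtures

Because the package must run without external measurements, it ships
closed-form synthetic fixtures with optional log-normal noise, all
requiring an explicit seed:

* `generate_reference_pdd()` — a 6 MV-like depth-dose curve
  $D(d) \propto (1 - e^{-\alpha d})\,e^{-\beta d}$ with its maximum
  exactly at 1.5 cm;
* `generate_reference_profile()` — a flat profile with error-function
  penumbra whose 50% level sits exactly on the geometric field edge;
* `generate_tld_fixture()` — point doses with multiplicative reading
  noise, for `run_tld_verification()` of the six midline TLD cells.

`compute_pdd()` and `compute_profile()` run the actual engine in a
water tank (`build_water_phantom()`), and `dta()` scores
distance-to-agreement between engine curves and fixtures in the
high-gradient regions.

```{r}
pdd <- compute_pdd(n_histories = 2e5, seed = 77, spectra = spectra)
ref <- generate_reference_pdd(depths = seq(0.05, 30, 0.05),
                              noise_sd = 0, seed = 1)
dta(pdd$depth_cm, pdd$dose, ref$depth_cm, ref$dose)
autoplot(pdd)
```

## Reproducing the full study

`scripts/acceptance.R` chains everything — both phantom sizes, both
plans, the treatment simulations, the organ-dose reports, the TLD
verification, and the water-tank curves — and writes one JSON file of
results:

```sh
Rscript scripts/acceptance.R --seed 1 --out results.json
```

All randomness derives from `--seed`; rerunning with the same seed
reproduces the file bit for bit.
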