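# Generates the bundled step-one beam spectra (inst/extdata/beam/spectra.tsv).
# Run from the repository root: Rscript data-raw/make_beam_spectra.R

pkgload::load_all(".", quiet = TRUE)
dir.create("inst/extdata/beam", recursive = TRUE, showWarnings = FALSE)
sp <- simulate_head(2e6, seed = 20130613)
write_beam_spectra(sp, "inst/extdata/beam/spectra.tsv")
message("wrote inst/extdata/beam/spectra.tsv")
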