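# Generates the bundled photon coefficient tables (inst/extdata/xs/*.tsv)
# from the package's cross-section model. Run from the repository root:
#   Rscript data-raw/make_coefficient_tables.R
# The generated TSVs are committed so installation never recomputes them.

pkgload::load_all(".", quiet = TRUE)

dir.create("inst/extdata/xs", recursive = TRUE, showWarnings = FALSE)
lib <- pd_material_library()
for (i in seq_len(nrow(lib))) {
  tab <- compute_coefficient_table(lib$composition[[i]])
  tab <- as.data.frame(lapply(tab, signif, digits = 7))
  path <- file.path("inst/extdata/xs", paste0(lib$material[i], ".tsv"))
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  message("wrote ", path)
}

# Material compositions as plain text alongside the tables.
rows <- do.call(rbind, lapply(seq_len(nrow(lib)), function(i) {
  comp <- lib$composition[[i]]
  data.frame(
    material = lib$material[i], density = lib$density[i],
    element = names(comp), mass_fraction = unname(comp)
  )
}))
write.table(rows, "inst/extdata/xs/compositions.tsv",
  sep = "\t", row.names = FALSE, quote = FALSE
)
message("wrote inst/extdata/xs/compositions.tsv")
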