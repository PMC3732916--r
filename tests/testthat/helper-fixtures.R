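# Write a small synthetic multi-species study to disk and return a pipeline
# configuration pointing at it. Three toy "species" share two conserved
# module processes; later species gain a derived one.
write_species_fixture <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  species <- list(
    list(name = "alga", terms = list(c("light"), c("starch"))),
    list(name = "moss", terms = list(c("light"), c("starch", "chem"))),
    list(name = "plant", terms = list(c("light"), c("starch", "chem")))
  )
  entries <- list()
  for (i in seq_along(species)) {
    sp <- species[[i]]
    mods <- list(
      list(module_id = "M1", gene_count = 22, within_correlation = 0.92,
           annotation_terms = sp$terms[[1]]),
      list(module_id = "M2", gene_count = 22, within_correlation = 0.92,
           annotation_terms = sp$terms[[2]]))
    spec <- compendium_spec(160, 12, 3, mods, seed = seed * 10 + i)
    comp <- generate_compendium(spec, species = sp$name)
    ann <- generate_annotations(comp, terms_per_gene_noise = 0.05,
                                term_pool = c("light", "starch", "chem",
                                              "noiseA", "noiseB"))
    spd <- file.path(dir, sp$name)
    dir.create(spd, showWarnings = FALSE)
    write_expression_table(comp, file.path(spd, "expr.tsv"),
                           file.path(spd, "meta.tsv"))
    write_annotation_table(ann, file.path(spd, "annot.tsv"))
    focal <- comp$truth$modules$M1[1:2]
    writeLines(focal, file.path(spd, "focal.txt"))
    markers <- data.frame(gene = c(comp$truth$modules$M1[3],
                                   comp$truth$modules$M2[3]),
                          label = c("light", "starch"))
    coexflow:::write_tsv_plain(markers, file.path(spd, "markers.tsv"))
    entries[[i]] <- list(name = sp$name,
                         expression = file.path(spd, "expr.tsv"),
                         metadata = file.path(spd, "meta.tsv"),
                         annotation = file.path(spd, "annot.tsv"),
                         focal_genes = file.path(spd, "focal.txt"),
                         markers = file.path(spd, "markers.tsv"))
  }
  list(species = entries,
       species_order = c("alga", "moss", "plant"),
       params = list(band = c(5, 25), target_degree = 15),
       out_dir = file.path(dir, "out"), seed = seed)
}
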