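#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a nine-protein CESA panel (three PCW
# plus two of each SCW ortholog type), gene models realizing the wheat CesA
# intron-phase assignments, the showcase protein family evolved on a known
# tree, and a two-group organ-by-stage count matrix. Ground truth for every
# object is kept as a JSON sidecar so downstream stages can be checked.

suppressPackageStartupMessages({
  library(cesafam)
  library(jsonlite)
})

seed <- 1L
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## protein panel -----------------------------------------------------------
panel <- make_protein_panel(seed = seed)
write_fasta(panel$proteins, file.path(out, "cesa_panel.fasta"))
truth_panel <- lapply(panel$truths, function(t) t[c("wall_class", "ortholog_type",
                                                    "znf_variant", "seed")])
names(truth_panel) <- vapply(panel$proteins, `[[`, "", "id")

## gene models for the four published phase assignments ---------------------
sets <- cesa_phase_sets()
models <- lapply(names(sets), function(nm) {
  make_gene_model(sets[[nm]], gene_id = nm, seed = seed + match(nm, names(sets)))$model
})
names(models) <- names(sets)
write_gene_models(models, file.path(out, "cesa_models.gff3"))

## showcase family (fixed seed 42: the documented demonstration fixture) ----
fam <- showcase_family(seed = 42L)
write_alignment(fam$alignment, file.path(out, "showcase_family.fasta"))

## two-group expression counts ----------------------------------------------
mc <- make_counts(seed = 7L)
write_counts(mc$counts, file.path(out, "counts.tsv"))

write_json(
  list(
    seed = seed,
    panel = truth_panel,
    phase_sets = lapply(sets, as.integer),
    showcase_groups = as.list(fam$groups),
    expression_groups = as.list(mc$truth$group)
  ),
  file.path(out, "ground_truth.json"),
  auto_unbox = TRUE, pretty = TRUE
)

cat(sprintf("simulated: %d proteins, %d gene models, %d-leaf family, %dx%d counts\n",
            length(panel$proteins), length(models),
            nrow(fam$alignment), nrow(mc$counts), ncol(mc$counts)))
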