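#!/usr/bin/env Rscript
# Domain annotation and wall classification of the simulated CESA panel:
# zinc finger (full or deletion variant), D/DXD/D/QXXRW catalytic core,
# transmembrane topology, and the PCW/SCW call from the two diagnostic
# motifs. Verifies the calls against the recorded ground truth.

suppressPackageStartupMessages({
  library(cesafam)
  library(jsonlite)
})

fasta <- "results/simulated/cesa_panel.fasta"
if (!file.exists(fasta)) stop("run analysis/01_simulate.R first")
res <- run_profile(fasta, "results/profile")

truth <- fromJSON("results/simulated/ground_truth.json")$panel
calls <- res$wall_calls
calls$truth <- vapply(calls$protein_id, function(id) truth[[id]]$wall_class, "")
n_ok <- sum(calls$call == calls$truth)

tmd_counts <- table(res$annotation$protein_id[grepl("^tmd", res$annotation$feature)])
cat(sprintf("classified %d/%d proteins correctly (all high confidence: %s)\n",
            n_ok, nrow(calls), all(calls$confidence == "high")))
cat(sprintf("transmembrane segments per protein: %s\n",
            paste(sort(unique(as.integer(tmd_counts))), collapse = ",")))
cat("reports: ", paste(res$paths, collapse = ", "), "\n")
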