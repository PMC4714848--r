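# Stage orchestration: thin wrappers that read the standard input formats,
# run one analysis stage, and write TSV/Newick reports with a provenance
# header. These are what the numbered analysis drivers call.

report_header <- function(params) {
  sprintf("# cesafam %s | %s | %s",
          as.character(utils::packageVersion("cesafam")),
          format(Sys.time(), "%Y-%m-%d"),
          paste(names(params), unlist(params), sep = "=", collapse = " "))
}

write_report <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(report_header(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stage report written by the pipeline
#' @param path Report path (TSV with one `#` header line).
#' @return Data frame.
#' @export
read_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Profile stage: domain annotation and wall classification
#'
#' Annotates every protein in a FASTA file (zinc finger, catalytic
#' signature, transmembrane segments, optional extra motifs) and classifies
#' it as PCW or SCW; writes `annotation.tsv` and `wall_calls.tsv` (1-based
#' inclusive coordinates) into `out_dir`.
#'
#' @param fasta Path to a protein FASTA file.
#' @param out_dir Output directory (created if needed).
#' @param motif_table Optional motif-table config path (see
#'   [read_motif_table()]).
#' @param tmd_window,tmd_threshold Hydropathy caller parameters.
#' @return Invisibly, a list with both report data frames and their paths.
#' @export
run_profile <- function(fasta, out_dir, motif_table = NULL,
                        tmd_window = 19L, tmd_threshold = 1.6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  proteins <- read_fasta(fasta)
  extra <- if (!is.null(motif_table)) read_motif_table(motif_table) else list()
  ann_rows <- list()
  for (p in proteins) {
    a <- annotate_domains(p, extra, tmd_window, tmd_threshold)
    rows <- data.frame(protein_id = character(0), feature = character(0),
                       start = integer(0), end = integer(0),
                       detail = character(0), stringsAsFactors = FALSE)
    if (a$znf$variant != "none") {
      rows <- rbind(rows, data.frame(
        protein_id = p$id, feature = "znf",
        start = a$znf$hit$start + 1L, end = a$znf$hit$end,
        detail = sprintf("%s;deletion=%d", a$znf$variant, a$znf$deletion_size)))
    }
    if (a$catalytic$present) {
      rows <- rbind(rows, data.frame(
        protein_id = p$id, feature = "catalytic",
        start = a$catalytic$d1 + 1L, end = a$catalytic$qxxrw + 5L,
        detail = sprintf("D1=%d;D2=%d;D3=%d;QXXRW=%d",
                         a$catalytic$d1 + 1L, a$catalytic$d2 + 1L,
                         a$catalytic$d3 + 1L, a$catalytic$qxxrw + 1L)))
    }
    if (nrow(a$tmds)) {
      rows <- rbind(rows, data.frame(
        protein_id = p$id, feature = paste0("tmd", seq_len(nrow(a$tmds))),
        start = a$tmds[, "start"] + 1L, end = a$tmds[, "end"],
        detail = "hydropathy"))
    }
    if (nrow(a$class_motif_hits)) {
      rows <- rbind(rows, data.frame(
        protein_id = p$id, feature = a$class_motif_hits$pattern_name,
        start = a$class_motif_hits$start + 1L, end = a$class_motif_hits$end,
        detail = a$class_motif_hits$matched))
    }
    ann_rows[[p$id]] <- rows
  }
  annotation <- do.call(rbind, ann_rows)
  rownames(annotation) <- NULL
  calls <- classify_wall_table(proteins)
  params <- list(fasta = fasta, tmd_window = tmd_window, tmd_threshold = tmd_threshold)
  ann_path <- file.path(out_dir, "annotation.tsv")
  call_path <- file.path(out_dir, "wall_calls.tsv")
  write_report(annotation, ann_path, params)
  write_report(calls, call_path, params)
  invisible(list(annotation = annotation, wall_calls = calls,
                 paths = c(ann_path, call_path)))
}

#' Phase stage: intron phases and structure summary from gene models
#'
#' @param gff3 Path to a GFF3 file with CDS features.
#' @param out_dir Output directory.
#' @return Invisibly, list with `phases` (per-intron report), `summary`
#'   (per-gene phase percentages) and paths.
#' @export
run_phases <- function(gff3, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  models <- read_gene_models(gff3)
  vectors <- lapply(models, intron_phases)
  summ <- suppressWarnings(phase_summary(vectors))
  phase_path <- file.path(out_dir, "intron_phases.tsv")
  write_phase_report(vectors, phase_path)
  summary_path <- file.path(out_dir, "phase_summary.tsv")
  write_report(summ$per_gene, summary_path, list(gff3 = gff3))
  invisible(list(phases = vectors, summary = summ,
                 paths = c(phase_path, summary_path)))
}

#' Tree stage: Poisson-corrected NJ with bootstrap from an aligned FASTA
#'
#' @param aligned_fasta Path to an aligned protein FASTA (gap `-`).
#' @param out_dir Output directory.
#' @param replicates Bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return Invisibly, list with `tree` (supports in node labels),
#'   `distances`, and paths of the Newick and PHYLIP outputs.
#' @export
run_tree <- function(aligned_fasta, out_dir, replicates = 1000L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aln <- read_alignment(aligned_fasta)
  reduced <- complete_deletion(aln)
  dist <- poisson_distance(reduced)
  tree <- bootstrap_nj(aln, replicates = replicates, seed = seed)
  newick_path <- file.path(out_dir, "nj_tree.nwk")
  phylip_path <- file.path(out_dir, "poisson_distances.phylip")
  write_newick(tree, newick_path)
  write_phylip(dist, phylip_path)
  invisible(list(tree = tree, distances = dist,
                 paths = c(newick_path, phylip_path)))
}

#' Expression stage: CPM/log2/z-score heat-map matrix with Ward clustering
#'
#' @param counts_tsv Path to a gene-by-sample counts TSV.
#' @param out_dir Output directory.
#' @return Invisibly, list with the ordered `matrix`, both `hclust`
#'   objects, the two-group gene split, and output paths (heat-map TSV and
#'   two dendrograms in Newick form).
#' @export
run_expr <- function(counts_tsv, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- read_counts(counts_tsv)
  hm <- heatmap_matrix(counts)
  split <- top_split(hm$gene_hclust)
  mat_path <- file.path(out_dir, "heatmap_zscores.tsv")
  df <- data.frame(gene_id = rownames(hm$matrix),
                   as.data.frame(hm$matrix), check.names = FALSE)
  write_report(df, mat_path, list(counts = counts_tsv))
  gene_nwk <- file.path(out_dir, "gene_dendrogram.nwk")
  writeLines(hclust_newick(hm$gene_hclust), gene_nwk)
  paths <- c(mat_path, gene_nwk)
  if (!is.null(hm$sample_hclust)) {
    sample_nwk <- file.path(out_dir, "sample_dendrogram.nwk")
    writeLines(hclust_newick(hm$sample_hclust), sample_nwk)
    paths <- c(paths, sample_nwk)
  }
  invisible(list(matrix = hm$matrix, gene_hclust = hm$gene_hclust,
                 sample_hclust = hm$sample_hclust, split = split,
                 paths = paths))
}
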