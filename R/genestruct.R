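# Intron phases and gene-structure statistics.
#
# An intron's phase is its position relative to codon structure: phase 0
# sits between two codons, phase 1 after the first base of a codon, phase 2
# after the second. Equivalently, the phase of intron i is the cumulative
# coding length of exons 1..i, modulo 3 — phases depend only on coding-exon
# lengths in translation order, never on genomic strand.

#' Intron phases of a gene model
#'
#' Phase of intron i (the intron between coding exons i and i+1) is the
#' cumulative coding-exon length up to exon i, modulo 3.
#'
#' @param model A [gene_model].
#' @return Object of class `intron_phase_vector`: integer vector of phases
#'   in `{0,1,2}` (length = exons − 1; empty for single-exon genes) with
#'   attribute `gene_id`.
#' @export
intron_phases <- function(model) {
  len <- exon_lengths(model)
  phases <- if (length(len) < 2L) integer(0) else
    as.integer(cumsum(len)[-length(len)] %% 3L)
  structure(phases, gene_id = model$gene_id, class = "intron_phase_vector")
}

#' Summarize intron-phase usage across genes
#'
#' @param vectors List of phase vectors (as from [intron_phases()], or bare
#'   integer vectors; names are used as gene ids when attributes are
#'   absent). Genes with zero introns are excluded with a warning.
#' @return List with `per_gene` (data frame: gene_id, intron count, phase
#'   counts n0/n1/n2, full-precision percentages pct0/pct1/pct2 and
#'   round-half-up integer renderings), and `range` (min/max percentage
#'   across genes for each phase).
#' @export
phase_summary <- function(vectors) {
  if (!length(vectors)) {
    stop_cesafam("empty_input", "no phase vectors supplied")
  }
  ids <- vapply(seq_along(vectors), function(i) {
    gid <- attr(vectors[[i]], "gene_id")
    if (!is.null(gid)) gid
    else if (!is.null(names(vectors)) && nzchar(names(vectors)[i])) names(vectors)[i]
    else paste0("gene", i)
  }, "")
  keep <- lengths(vectors) > 0L
  if (any(!keep)) {
    warning(sprintf("excluding %d gene(s) with zero introns: %s",
                    sum(!keep), paste(ids[!keep], collapse = ", ")))
  }
  vectors <- vectors[keep]
  ids <- ids[keep]
  if (!length(vectors)) {
    stop_cesafam("empty_input", "all supplied genes have zero introns")
  }
  per_gene <- do.call(rbind, lapply(seq_along(vectors), function(i) {
    v <- as.integer(vectors[[i]])
    n <- length(v)
    cnt <- vapply(0:2, function(p) sum(v == p), 1L)
    pct <- 100 * cnt / n
    data.frame(
      gene_id = ids[i], introns = n,
      n0 = cnt[1], n1 = cnt[2], n2 = cnt[3],
      pct0 = pct[1], pct1 = pct[2], pct2 = pct[3],
      pct0_int = round_half_up(pct[1]), pct1_int = round_half_up(pct[2]),
      pct2_int = round_half_up(pct[3]),
      stringsAsFactors = FALSE
    )
  }))
  range_tab <- data.frame(
    phase = 0:2,
    min_pct = vapply(c("pct0", "pct1", "pct2"), function(cl) min(per_gene[[cl]]), 0),
    max_pct = vapply(c("pct0", "pct1", "pct2"), function(cl) max(per_gene[[cl]]), 0),
    row.names = NULL
  )
  list(per_gene = per_gene, range = range_tab)
}

# round-half-up to integer: 66.5 -> 67 (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

#' Gene-structure statistics
#'
#' Totals over a gene model within its genomic span: exon and intron
#' lengths, intron count, ORF length in amino acids (stop codon removed
#' before dividing by three), and the intron-phase tallies.
#'
#' @param model A [gene_model].
#' @param gene_span Length-2 numeric, 0-based half-open genomic interval
#'   covering all coding exons (defaults to the exon extent).
#' @return Object of class `gene_structure_stats`: list with `gene_id`,
#'   `gene_length`, `exon_total`, `intron_total`, `intron_count`,
#'   `orf_length`, `phase_counts` and `phase_proportions` (percent).
#' @export
structure_stats <- function(model, gene_span = NULL) {
  ex <- model$coding_exons
  extent <- c(min(ex[, "start"]), max(ex[, "end"]))
  if (is.null(gene_span)) gene_span <- extent
  if (gene_span[1] > extent[1] || gene_span[2] < extent[2]) {
    stop_cesafam("span_too_small",
                 sprintf("gene '%s': span does not cover the coding exons",
                         model$gene_id))
  }
  exon_total <- sum(exon_lengths(model))
  gene_length <- as.integer(gene_span[2] - gene_span[1])
  phases <- intron_phases(model)
  cnt <- vapply(0:2, function(p) sum(phases == p), 1L)
  structure(
    list(
      gene_id = model$gene_id,
      gene_length = gene_length,
      exon_total = exon_total,
      intron_total = gene_length - exon_total,
      intron_count = length(phases),
      orf_length = (exon_total - 3L) %/% 3L,
      phase_counts = stats::setNames(cnt, paste0("phase", 0:2)),
      phase_proportions = stats::setNames(
        if (length(phases)) 100 * cnt / length(phases) else rep(NA_real_, 3),
        paste0("phase", 0:2)
      )
    ),
    class = "gene_structure_stats"
  )
}

#' @export
print.gene_structure_stats <- function(x, ...) {
  cat(sprintf("<gene_structure_stats> %s: %d nt (%d exonic, %d intronic), %d intron(s), ORF %d aa\n",
              x$gene_id, x$gene_length, x$exon_total, x$intron_total,
              x$intron_count, x$orf_length))
  invisible(x)
}

#' Intron-phase assignments of the wheat CesA genes
#'
#' The four per-gene phase assignments of the wheat cellulose synthase
#' family, transcribed from the published description: the common pattern
#' shared by the PCW genes TaCesA1/2/6 (13 introns), and the patterns of
#' the SCW genes TaCesA4 (7 introns), TaCesA7 (12) and TaCesA8 (9).
#'
#' @return Named list of integer phase vectors.
#' @export
cesa_phase_sets <- function() {
  sets <- list(
    # introns 1,3,7,8,9,10,12,13 phase 0; 2,4,11 phase 1; 5,6 phase 2
    PCW_common = c(0L, 1L, 0L, 1L, 2L, 2L, 0L, 0L, 0L, 0L, 1L, 0L, 0L),
    # introns 2,5,6,7 phase 0; 1,3 phase 1; 4 phase 2
    TaCesA4 = c(1L, 0L, 1L, 2L, 0L, 0L, 0L),
    # introns 2,6,7,8,9,11,12 phase 0; 1,3,10 phase 1; 4,5 phase 2
    TaCesA7 = c(1L, 0L, 1L, 2L, 2L, 0L, 0L, 0L, 0L, 1L, 0L, 0L),
    # introns 1,4,5,6,8,9 phase 0; 2,7 phase 1; 3 phase 2
    TaCesA8 = c(0L, 1L, 2L, 0L, 0L, 0L, 1L, 0L, 0L)
  )
  lapply(sets, function(v) structure(v, class = "intron_phase_vector"))
}

#' Gene-structure profile of the wheat CesA family
#'
#' Published per-gene structure summary (gene length in nt, intron count,
#' ORF length in amino acids, wall class) for the nine wheat CesA genes.
#'
#' @return Data frame with columns `gene`, `wall`, `gene_length_nt`,
#'   `introns`, `orf_length_aa`.
#' @export
cesa_structure_table <- function() {
  data.frame(
    gene = paste0("TaCesA", 1:9),
    wall = c("PCW", "PCW", "PCW", "SCW", "PCW", "PCW", "SCW", "SCW", "PCW"),
    gene_length_nt = c(5175L, 5005L, 5127L, 3923L, 4085L, 5251L, 5072L, 4044L, 2184L),
    introns = c(13L, 13L, 13L, 7L, 14L, 13L, 12L, 9L, 5L),
    orf_length_aa = c(1080L, 1091L, 1105L, 1044L, 1078L, 1075L, 991L, 1055L, 537L),
    stringsAsFactors = FALSE
  )
}

#' Write per-intron phases as TSV
#' @param vectors List of phase vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phase_report <- function(vectors, path) {
  rows <- do.call(rbind, lapply(seq_along(vectors), function(i) {
    v <- vectors[[i]]
    gid <- attr(v, "gene_id")
    if (is.null(gid)) gid <- names(vectors)[i]
    if (!length(v)) return(NULL)
    data.frame(gene_id = gid, intron_index = seq_along(v), phase = as.integer(v),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
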