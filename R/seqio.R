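# The 20 canonical one-letter amino-acid codes. Ambiguity codes (B, J, O, U,
# X, Z) are deliberately rejected everywhere sequences enter the package.
AA_CANONICAL <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Construct a protein record
#'
#' A protein record is the package's unit of sequence: an identifier, an
#' optional free-text description, and an uppercase sequence over the 20
#' canonical amino-acid letters. A terminal stop symbol `*` (a common
#' exporter artifact) is stripped; any internal `*` or ambiguity letter is
#' rejected.
#'
#' @param id Character scalar identifier.
#' @param sequence Character scalar amino-acid sequence; lowercase accepted
#'   and normalized to uppercase.
#' @param description Optional free-text description.
#' @return An object of class `protein_record` with fields `id`,
#'   `description` and `sequence`.
#' @export
protein_record <- function(id, sequence, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  sequence <- sub("\\*$", "", sequence)
  if (!nzchar(sequence)) {
    stop_cesafam("empty_sequence", sprintf("record '%s' has an empty sequence", id))
  }
  bad <- which(!strsplit(sequence, "")[[1]] %in% AA_CANONICAL)
  if (length(bad)) {
    stop_cesafam(
      "illegal_residue",
      sprintf(
        "record '%s' has non-canonical residue '%s' at position %d",
        id, substr(sequence, bad[1], bad[1]), bad[1]
      )
    )
  }
  structure(
    list(id = id, description = description, sequence = sequence),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf(
    "<protein_record> %s (%d aa)%s\n", x$id, nchar(x$sequence),
    if (nzchar(x$description)) paste0(" ", x$description) else ""
  ))
  invisible(x)
}

# Named condition helper: every user-facing error in the package carries a
# subclass "cesafam_<name>" so callers and tests can match on it.
stop_cesafam <- function(name, message) {
  stop(structure(
    class = c(paste0("cesafam_", name), "cesafam_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Read a protein FASTA file
#'
#' Parsing is delegated to [Biostrings::readAAStringSet()]; records are then
#' validated against the canonical amino-acid alphabet (terminal `*`
#' stripped, lowercase uppercased).
#'
#' @param path Path to a FASTA file.
#' @return List of [protein_record] objects, one per header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop_cesafam("missing_file", sprintf("file not found: %s", path))
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    stop_cesafam("empty_fasta", sprintf("no FASTA records in %s", path))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  lapply(seq_along(set), function(i) {
    protein_record(ids[i], as.character(set[[i]]), descs[i])
  })
}

#' Write protein records to FASTA
#'
#' @param records List of [protein_record] objects.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, "")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Construct a gene model
#'
#' A gene model holds the ordered coding exons of one gene. Coordinates are
#' 0-based half-open internally (unambiguous length arithmetic); all GFF3
#' I/O converts to/from the 1-based inclusive external convention. Exons are
#' stored in translation order: ascending along the genome on `+`,
#' descending on `-`.
#'
#' @param gene_id Character scalar.
#' @param strand `"+"` or `"-"`.
#' @param coding_exons Two-column integer matrix `(start, end)`, 0-based
#'   half-open, one row per coding exon, rows in translation order.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, strand, coding_exons) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (!strand %in% c("+", "-")) {
    stop_cesafam("bad_strand", sprintf("gene '%s': strand must be + or -", gene_id))
  }
  coding_exons <- matrix(as.integer(coding_exons), ncol = 2L,
                         dimnames = list(NULL, c("start", "end")))
  if (nrow(coding_exons) == 0L) {
    stop_cesafam("empty_model", sprintf("gene '%s' has no coding exons", gene_id))
  }
  len <- coding_exons[, "end"] - coding_exons[, "start"]
  if (any(len < 1L)) {
    stop_cesafam("bad_exon", sprintf("gene '%s': exon of length < 1", gene_id))
  }
  if (sum(len) < 3L) {
    stop_cesafam("short_cds", sprintf("gene '%s': total coding length < 3", gene_id))
  }
  # overlap check on genomic order regardless of stored (translation) order
  ord <- order(coding_exons[, "start"])
  g <- coding_exons[ord, , drop = FALSE]
  if (nrow(g) > 1L && any(g[-nrow(g), "end"] > g[-1L, "start"])) {
    stop_cesafam("overlapping_exons", sprintf("gene '%s': overlapping coding exons", gene_id))
  }
  # translation order: ascending starts on +, descending on -
  starts <- coding_exons[, "start"]
  ok <- if (strand == "+") all(diff(starts) > 0) else all(diff(starts) < 0)
  if (nrow(coding_exons) > 1L && !ok) {
    stop_cesafam("bad_exon_order",
                 sprintf("gene '%s': exons not in translation order", gene_id))
  }
  structure(
    list(gene_id = gene_id, strand = strand, coding_exons = coding_exons),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %d coding exon(s), CDS %d nt\n",
              x$gene_id, x$strand, nrow(x$coding_exons),
              sum(x$coding_exons[, "end"] - x$coding_exons[, "start"])))
  invisible(x)
}

#' Exon lengths of a gene model, in translation order
#' @param model A [gene_model].
#' @return Integer vector of exon lengths (nt).
#' @export
exon_lengths <- function(model) {
  unname(model$coding_exons[, "end"] - model$coding_exons[, "start"])
}

#' Read gene models from a GFF3 file
#'
#' Only `CDS` features are used; they are grouped per gene by the `Parent`
#' attribute (falling back to `ID`), sorted into translation order and
#' converted from GFF3's 1-based inclusive coordinates to the 0-based
#' half-open internal convention.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of [gene_model] objects, in order of first appearance.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) {
    stop_cesafam("missing_file", sprintf("file not found: %s", path))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(gr) == 0L) {
    stop_cesafam("no_cds", sprintf("no CDS features in %s", path))
  }
  parent <- if (!is.null(gr$Parent)) {
    vapply(as.list(gr$Parent), function(p) if (length(p)) p[[1]] else NA_character_, "")
  } else {
    rep(NA_character_, length(gr))
  }
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  key <- ifelse(is.na(parent) | !nzchar(parent), ids, parent)
  if (anyNA(key)) {
    stop_cesafam("missing_attributes", "CDS feature without Parent or ID attribute")
  }
  out <- lapply(unique(key), function(k) {
    sub <- gr[key == k]
    strands <- unique(as.character(GenomicRanges::strand(sub)))
    if (length(strands) != 1L || !strands %in% c("+", "-")) {
      stop_cesafam("mixed_strands", sprintf("gene '%s': mixed or missing strands", k))
    }
    start0 <- GenomicRanges::start(sub) - 1L   # 1-based inclusive -> 0-based half-open
    end0 <- GenomicRanges::end(sub)
    ord <- if (strands == "+") order(start0) else order(start0, decreasing = TRUE)
    gene_model(k, strands, cbind(start0[ord], end0[ord]))
  })
  names(out) <- unique(key)
  out
}

#' Write gene models to a GFF3 file
#'
#' Emits one `CDS` line per coding exon (1-based inclusive coordinates) with
#' a `Parent` attribute carrying the gene id, via [rtracklayer::export()].
#'
#' @param models List of [gene_model] objects.
#' @param path Output path.
#' @param seqname Sequence (chromosome) name to write.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path, seqname = "chr1") {
  rows <- do.call(rbind, lapply(models, function(m) {
    len <- m$coding_exons[, "end"] - m$coding_exons[, "start"]
    before <- c(0L, cumsum(len))[seq_along(len)]
    data.frame(
      start = m$coding_exons[, "start"] + 1L,   # back to 1-based inclusive
      end = m$coding_exons[, "end"],
      strand = m$strand,
      parent = m$gene_id,
      # GFF3 CDS phase: bases to skip to reach the next codon start
      phase = (3L - before %% 3L) %% 3L,
      stringsAsFactors = FALSE
    )
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = rows$strand
  )
  gr$type <- "CDS"
  gr$source <- "cesafam"
  gr$phase <- rows$phase
  gr$ID <- paste0(rows$parent, ".cds",
                  stats::ave(rows$start, rows$parent, FUN = seq_along))
  gr$Parent <- rows$parent
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a gene-by-sample counts table
#'
#' Expects a tab-separated file whose first column holds gene ids and whose
#' header row holds sample ids; all cells must be non-negative integers.
#'
#' @param path Path to the TSV file.
#' @return A `counts_matrix`: an integer matrix with gene ids as rownames
#'   and sample ids as colnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) {
    stop_cesafam("missing_file", sprintf("file not found: %s", path))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    stop_cesafam("empty_counts", sprintf("no data rows in %s", path))
  }
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids)) {
    stop_cesafam("duplicate_ids",
                 sprintf("duplicate gene id '%s'", gene_ids[duplicated(gene_ids)][1]))
  }
  vals <- df[, -1, drop = FALSE]
  if (anyDuplicated(colnames(vals))) {
    stop_cesafam("duplicate_ids", "duplicate sample id in header")
  }
  m <- as.matrix(vals)
  suppressWarnings(storage.mode(m) <- "double")
  bad <- which(is.na(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_cesafam("bad_count", sprintf(
      "non-numeric or negative count at gene '%s', sample '%s'",
      gene_ids[bad[1, 1]], colnames(vals)[bad[1, 2]]
    ))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- gene_ids
  counts_matrix(m)
}

#' Construct a counts matrix
#'
#' @param m Integer matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids).
#' @return The validated matrix with class `counts_matrix`.
#' @export
counts_matrix <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop_cesafam("duplicate_ids", "duplicate gene or sample ids")
  }
  if (any(m < 0) || any(m != floor(m))) {
    stop_cesafam("bad_count", "counts must be non-negative integers")
  }
  if (any(colSums(m) <= 0)) {
    stop_cesafam("zero_library",
                 sprintf("sample '%s' has zero library size",
                         colnames(m)[colSums(m) <= 0][1]))
  }
  storage.mode(m) <- "integer"
  class(m) <- c("counts_matrix", class(m))
  m
}

#' Write a counts matrix as TSV
#' @param counts A `counts_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), as.data.frame(unclass(counts)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an aligned FASTA file into an alignment matrix
#'
#' Rows are sequences, columns alignment positions; the gap character is
#' `-`. All rows must be the same length.
#'
#' @param path Path to aligned FASTA.
#' @return Character matrix with sequence ids as rownames, class `alignment`.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    stop_cesafam("empty_fasta", sprintf("no FASTA records in %s", path))
  }
  alignment_matrix(
    vapply(seq_along(set), function(i) toupper(as.character(set[[i]])), ""),
    sub("\\s.*$", "", names(set))
  )
}

#' Build an alignment matrix from aligned sequence strings
#' @param seqs Character vector of equal-length aligned sequences.
#' @param ids Sequence identifiers.
#' @return Character matrix (rows = sequences), class `alignment`.
#' @export
alignment_matrix <- function(seqs, ids = names(seqs)) {
  if (length(unique(nchar(seqs))) != 1L) {
    stop_cesafam("ragged_alignment", "aligned sequences differ in length")
  }
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- ids
  class(m) <- c("alignment", class(m))
  m
}

#' Write an alignment matrix to aligned FASTA
#' @param aln An `alignment` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1, paste0, collapse = "")
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- rownames(aln)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
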