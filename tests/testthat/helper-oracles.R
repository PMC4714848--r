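# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the motif oracle tests every offset by direct
# character comparison, the phase oracle tiles codons explicitly.

# Brute-force degenerate-pattern matcher: parse the spec into single-token
# characters (fixed letter or "X" wildcard), then test every offset.
brute_force_scan <- function(seq, spec) {
  tokens <- character(0)
  chars <- strsplit(gsub("[-()[:space:]]", "", spec), "")[[1]]
  i <- 1
  while (i <= length(chars)) {
    if (chars[i] == "X") {
      j <- i + 1
      digits <- ""
      while (j <= length(chars) && grepl("[0-9]", chars[j])) {
        digits <- paste0(digits, chars[j]); j <- j + 1
      }
      rep_n <- if (nzchar(digits)) as.integer(digits) else 1L
      tokens <- c(tokens, rep("X", rep_n))
      i <- j
    } else {
      tokens <- c(tokens, chars[i])
      i <- i + 1
    }
  }
  k <- length(tokens)
  s <- strsplit(seq, "")[[1]]
  hits <- integer(0)
  if (k <= length(s)) {
    for (off in 0:(length(s) - k)) {
      window <- s[(off + 1):(off + k)]
      if (all(tokens == "X" | tokens == window)) hits <- c(hits, off)
    }
  }
  hits
}

# Codon-tiling intron-phase oracle: lay codon positions 1,2,3 explicitly
# over the concatenated CDS; the phase of the intron after cumulative
# length b is (codon position of base b+1) - 1.
codon_tiling_phases <- function(exon_lens) {
  total <- sum(exon_lens)
  codon_pos <- rep(1:3, length.out = total)
  boundaries <- cumsum(exon_lens)[-length(exon_lens)]
  if (!length(boundaries)) return(integer(0))
  codon_pos[boundaries + 1] - 1L
}

# A random plus-strand gene model with the given exon lengths.
model_from_lengths <- function(lens, gene_id = "g", strand = "+",
                               intron_len = 50L) {
  pos <- 0L
  exons <- matrix(0L, length(lens), 2)
  for (i in seq_along(lens)) {
    exons[i, ] <- c(pos, pos + lens[i])
    pos <- pos + lens[i] + intron_len
  }
  if (strand == "-") {
    total <- max(exons[, 2])
    exons <- cbind(total - exons[, 2], total - exons[, 1])
  }
  gene_model(gene_id, strand, exons)
}

random_protein_string <- function(n, alphabet = c("A", "C", "G", "Q")) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}
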