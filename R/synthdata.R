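# Seeded synthetic-data generators. Every generated object carries a
# ground-truth record sufficient to serve as the oracle for the module that
# consumes it: motif coordinates and class labels for proteins, the
# generating tree for evolved families, the requested phase vector for gene
# models, group labels and design for count matrices.
#
# Alphabet discipline keeps the ground truth unambiguous: cysteine and
# tryptophan occur only at motif-fixed positions (so the zinc finger, the
# TM2 motif core and QXXRW cannot arise spuriously), linker/filler residues
# are drawn from a strictly hydrophilic alphabet (every Kyte-Doolittle
# value < 0, so no spurious transmembrane window), and aspartate is banned
# from fillers inside the catalytic region (so the nearest-neighbor
# D/DXD/D search resolves to the planted residues).

# hydrophilic fillers: KD < 0 throughout, no C/W
SPACER_ALPHABET <- c("G", "S", "T", "N", "Q", "E", "K", "P", "H", "D", "R", "Y")
# same, minus D, for fillers inside the catalytic region
CATALYTIC_FILLER <- setdiff(SPACER_ALPHABET, "D")
# transmembrane segments
TMD_ALPHABET <- c("A", "I", "L", "F", "V", "M")

TM2_MOTIF_BY_TYPE <- list(
  "PCW-type"   = c("S", "V", "I", "C", "E", NA, "W", "F", "A"),
  "CesA4-like" = c("S", "V", "L", "C", "E", NA, "W", "F", "A"),
  "CesA7-like" = c("S", "V", "I", "C", "E", NA, "W", "F", "G"),
  "CesA8-like" = c("S", "I", "V", "C", "E", NA, "W", "F", "A")
)
ZNF_DIPEPTIDE_BY_TYPE <- list(
  "PCW-type" = "QI", "CesA4-like" = "EI", "CesA7-like" = "AA", "CesA8-like" = "RA"
)

#' Synthesis template for a CESA-like protein
#'
#' @param wall_class `"PCW"` or `"SCW"`.
#' @param ortholog_type `"PCW-type"` (required for PCW) or one of
#'   `"CesA4-like"`, `"CesA7-like"`, `"CesA8-like"` (SCW; default
#'   `"CesA4-like"`).
#' @param target_length Total protein length in residues; by default drawn
#'   from the class-typical range (1075-1091 for PCW, 991-1055 for SCW).
#' @param znf_variant `"full_46"` or `"deleted_38"`; `"CesA7-like"` forces
#'   `"deleted_38"`, all other types default to `"full_46"`.
#' @param seed Integer RNG seed.
#' @return Object of class `cesa_template`.
#' @export
cesa_template <- function(wall_class = c("PCW", "SCW"), ortholog_type = NULL,
                          target_length = NULL, znf_variant = NULL, seed = 1L) {
  wall_class <- match.arg(wall_class)
  if (is.null(ortholog_type)) {
    ortholog_type <- if (wall_class == "PCW") "PCW-type" else "CesA4-like"
  }
  if (wall_class == "PCW" && ortholog_type != "PCW-type") {
    stop_cesafam("bad_template", "PCW templates must use ortholog_type 'PCW-type'")
  }
  if (wall_class == "SCW" &&
      !ortholog_type %in% c("CesA4-like", "CesA7-like", "CesA8-like")) {
    stop_cesafam("bad_template", "SCW templates need an SCW ortholog_type")
  }
  if (ortholog_type == "CesA7-like") {
    if (!is.null(znf_variant) && znf_variant != "deleted_38") {
      stop_cesafam("bad_template", "CesA7-like templates force znf_variant 'deleted_38'")
    }
    znf_variant <- "deleted_38"
  } else if (is.null(znf_variant)) {
    znf_variant <- "full_46"
  }
  if (!znf_variant %in% c("full_46", "deleted_38")) {
    stop_cesafam("bad_template", "znf_variant must be 'full_46' or 'deleted_38'")
  }
  structure(
    list(wall_class = wall_class, ortholog_type = ortholog_type,
         target_length = target_length, znf_variant = znf_variant,
         seed = as.integer(seed)),
    class = "cesa_template"
  )
}

draw_from <- function(alphabet, n) {
  if (n <= 0L) character(0) else sample(alphabet, n, replace = TRUE)
}

# Instantiate a compiled degenerate pattern: fixed residues kept, wildcards
# filled from `fill`. Returns a character vector of residues.
instantiate_pattern <- function(pattern, fill = SPACER_ALPHABET) {
  unlist(lapply(pattern$elements, function(e) {
    if (e$type == "fixed") e$residue else draw_from(fill, e$n)
  }))
}

#' Generate a synthetic CESA-like protein with ground truth
#'
#' Builds a protein realizing the canonical CESA domain layout: an
#' N-terminal zinc finger (46-AA consensus or the 38-AA deletion variant)
#' carrying the class-diagnostic CXXC dipeptide, two N-terminal
#' transmembrane segments with the class-diagnostic TM2 motif embedded in
#' the second, a central catalytic region with the D, DXD, D, QXXRW
#' signature, and six C-terminal transmembrane segments. All coordinates
#' and labels are recorded as ground truth.
#'
#' @param template A [cesa_template()].
#' @return List with `protein` (a [protein_record]) and `truth` (named
#'   list: class labels, 0-based coordinates of the zinc finger, TM2 motif,
#'   catalytic residues and all eight TMD intervals, and the seed).
#' @export
make_cesa_protein <- function(template = cesa_template()) {
  stopifnot(inherits(template, "cesa_template"))
  set.seed(template$seed)
  tl <- template$target_length
  if (is.null(tl)) {
    tl <- if (template$wall_class == "PCW") sample(1075:1091, 1L) else sample(991:1055, 1L)
  }

  # zinc finger with the diagnostic dipeptide at offsets 1-2
  znf_pat <- compile_pattern(ZNF_PATTERNS[[template$znf_variant]], "znf")
  znf <- instantiate_pattern(znf_pat)
  dip <- strsplit(ZNF_DIPEPTIDE_BY_TYPE[[template$ortholog_type]], "")[[1]]
  znf[2:3] <- dip

  # TM2: class motif embedded in a 21-residue hydrophobic segment
  motif <- TM2_MOTIF_BY_TYPE[[template$ortholog_type]]
  motif[is.na(motif)] <- draw_from(TMD_ALPHABET, 1L)
  tm2_offset <- sample(3:10, 1L)                      # motif offset inside TMD2
  tm2 <- draw_from(TMD_ALPHABET, 21L)
  tm2[tm2_offset + seq_along(motif)] <- motif

  # catalytic core pieces (fillers exclude D so nearest-neighbor search is
  # unambiguous; QXXRW wildcards exclude D by construction of the alphabet)
  dxd <- c("D", draw_from(CATALYTIC_FILLER, 1L), "D")
  qxxrw <- c("Q", draw_from(CATALYTIC_FILLER, 1L), draw_from(CATALYTIC_FILLER, 1L), "R", "W")
  gap_a <- sample(12:25, 1L)   # D1 .. DXD
  gap_b <- sample(12:25, 1L)   # DXD .. D3
  gap_c <- sample(12:25, 1L)   # D3 .. QXXRW

  tmd_len <- 21L
  n_cterm <- 6L
  inter_tmd <- 25L
  fixed <- 30L + length(znf) + 40L + tmd_len + 30L + tmd_len + 30L +
    30L + (1L + gap_a + 3L + gap_b + 1L + gap_c + 5L) + 30L +
    n_cterm * tmd_len + (n_cterm - 1L) * inter_tmd + 15L
  pad <- tl - fixed
  if (pad < 0L) {
    stop_cesafam("target_too_small",
                 sprintf("target_length %d cannot host the domain layout (need >= %d)",
                         tl, fixed))
  }
  pad_pre <- pad %/% 2L          # extra catalytic flank before D1
  pad_post <- pad - pad_pre      # extra flank after QXXRW

  pieces <- list(
    nter    = draw_from(SPACER_ALPHABET, 30L),
    znf     = znf,
    link1   = draw_from(SPACER_ALPHABET, 40L),
    tmd1    = draw_from(TMD_ALPHABET, tmd_len),
    link2   = draw_from(SPACER_ALPHABET, 30L),
    tmd2    = tm2,
    link3   = draw_from(SPACER_ALPHABET, 30L),
    cat_pre = draw_from(CATALYTIC_FILLER, 30L + pad_pre),
    d1      = "D",
    gap_a   = draw_from(CATALYTIC_FILLER, gap_a),
    dxd     = dxd,
    gap_b   = draw_from(CATALYTIC_FILLER, gap_b),
    d3      = "D",
    gap_c   = draw_from(CATALYTIC_FILLER, gap_c),
    qxxrw   = qxxrw,
    cat_post = draw_from(CATALYTIC_FILLER, 30L + pad_post)
  )
  for (k in seq_len(n_cterm)) {
    pieces[[paste0("tmd", k + 2L)]] <- draw_from(TMD_ALPHABET, tmd_len)
    if (k < n_cterm) {
      pieces[[paste0("clink", k)]] <- draw_from(SPACER_ALPHABET, inter_tmd)
    }
  }
  pieces$cter <- draw_from(SPACER_ALPHABET, 15L)

  lens <- vapply(pieces, length, 1L)
  offsets <- cumsum(c(0L, lens))[seq_along(pieces)]   # 0-based start of each piece
  names(offsets) <- names(pieces)
  seq <- paste0(unlist(pieces), collapse = "")

  tmd_names <- c("tmd1", "tmd2", paste0("tmd", 3:8))
  truth <- list(
    wall_class = template$wall_class,
    ortholog_type = template$ortholog_type,
    znf_variant = template$znf_variant,
    znf_dipeptide = paste0(dip, collapse = ""),
    znf_start = unname(offsets["znf"]),
    znf_end = unname(offsets["znf"] + lens["znf"]),
    tm2_motif_start = unname(offsets["tmd2"] + tm2_offset),
    d1 = unname(offsets["d1"]),
    d2 = unname(offsets["dxd"]),
    d3 = unname(offsets["d3"]),
    qxxrw = unname(offsets["qxxrw"]),
    tmds = cbind(start = unname(offsets[tmd_names]),
                 end = unname(offsets[tmd_names] + tmd_len)),
    length = nchar(seq),
    seed = template$seed
  )
  id <- sprintf("syn_%s_%s_s%d",
                tolower(template$wall_class),
                gsub("-like", "", tolower(template$ortholog_type)),
                template$seed)
  list(protein = protein_record(id, seq,
                                sprintf("synthetic %s CESA (%s)",
                                        template$wall_class, template$ortholog_type)),
       truth = truth)
}

#' Positions to protect from substitution for a generated protein
#'
#' The zinc finger, the TM2 diagnostic motif (including the residue after
#' the F), and the catalytic D/DXD/D/QXXRW residues, as 0-based positions.
#'
#' @param truth Ground-truth record from [make_cesa_protein()].
#' @return Sorted integer vector of 0-based protected positions.
#' @export
protected_positions <- function(truth) {
  sort(unique(c(
    truth$znf_start:(truth$znf_end - 1L),
    truth$tm2_motif_start:(truth$tm2_motif_start + 8L),
    truth$d1, truth$d2:(truth$d2 + 2L), truth$d3,
    truth$qxxrw:(truth$qxxrw + 4L)
  )))
}

#' Evolve a protein family along a tree
#'
#' A Poisson substitution process: along each branch, each site receives a
#' Poisson(branch length) number of replacement events, each replacing the
#' residue with a uniformly chosen different residue. Protected positions
#' (e.g. diagnostic motifs) are never touched. No indels, so the leaf set
#' is its own (gap-free) alignment.
#'
#' @param root A [protein_record], the ancestral sequence.
#' @param tree A rooted `ape::phylo` with branch lengths in expected
#'   substitutions per site; tip labels become row ids.
#' @param protect Integer vector of 0-based positions immune to
#'   substitution (e.g. [protected_positions()]); `NULL` for none.
#' @param seed Integer RNG seed.
#' @return An `alignment` matrix (tips x sites) with attribute `tree` (the
#'   generating tree).
#' @export
evolve_family <- function(root, tree, protect = NULL, seed = 1L) {
  stopifnot(inherits(root, "protein_record"), inherits(tree, "phylo"))
  set.seed(seed)
  root_chars <- strsplit(root$sequence, "")[[1]]
  L <- length(root_chars)
  mutable <- setdiff(seq_len(L), if (is.null(protect)) integer(0) else protect + 1L)

  mutate_branch <- function(chars, bl) {
    if (bl <= 0) return(chars)
    k <- stats::rpois(length(mutable), bl)
    for (idx in which(k > 0L)) {
      pos <- mutable[idx]
      for (e in seq_len(k[idx])) {
        chars[pos] <- sample(setdiff(AA_CANONICAL, chars[pos]), 1L)
      }
    }
    chars
  }

  n_tip <- length(tree$tip.label)
  root_node <- n_tip + 1L
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root_node]] <- root_chars
  # parents precede children in a preorder edge walk
  edge_order <- ape::reorder.phylo(tree, "cladewise")$edge
  bl <- tree$edge.length[match(
    paste(edge_order[, 1], edge_order[, 2]),
    paste(tree$edge[, 1], tree$edge[, 2])
  )]
  for (e in seq_len(nrow(edge_order))) {
    parent <- edge_order[e, 1]
    child <- edge_order[e, 2]
    seqs[[child]] <- mutate_branch(seqs[[parent]], bl[e])
  }
  aln <- do.call(rbind, seqs[seq_len(n_tip)])
  rownames(aln) <- tree$tip.label
  class(aln) <- c("alignment", class(aln))
  attr(aln, "tree") <- tree
  aln
}

#' The showcase CESA family
#'
#' A fixed demonstration family: three ortholog groups (deep, well
#' separated clades) sampled in three species each, evolved from one
#' synthetic CESA root with diagnostic motifs protected. Mirrors the
#' expectation that orthologs from different species group together before
#' paralogs.
#'
#' @param seed Integer seed (default 42, the documented showcase).
#' @param ortholog_branch Length of the branch subtending each ortholog
#'   clade (substitutions/site).
#' @param species_branch Terminal branch length within a clade.
#' @return List with `alignment`, `tree` (the generating tree), `root`
#'   (protein + truth) and `groups` (named vector: tip -> ortholog group).
#' @export
showcase_family <- function(seed = 42L, ortholog_branch = 0.4,
                            species_branch = 0.05) {
  gen <- make_cesa_protein(cesa_template("PCW", seed = seed))
  groups <- c("CesA4", "CesA7", "CesA8")
  species <- c("sp1", "sp2", "sp3")
  clades <- vapply(groups, function(g) {
    tips <- paste(g, species, sep = "_")
    sprintf("(%s):%s", paste0(tips, ":", species_branch, collapse = ","),
            ortholog_branch)
  }, "")
  tree <- ape::read.tree(text = sprintf("(%s);", paste(clades, collapse = ",")))
  aln <- evolve_family(gen$protein, tree,
                       protect = protected_positions(gen$truth), seed = seed)
  group_of <- stats::setNames(rep(groups, each = length(species)), tree$tip.label)
  list(alignment = aln, tree = tree, root = gen, groups = group_of)
}

#' Generate a gene model realizing a requested intron-phase vector
#'
#' Exon lengths are drawn (each at least 30 nt) such that the cumulative
#' coding length modulo 3 reproduces the requested phases, and the total
#' coding length is a multiple of three. Intron lengths are drawn from
#' `intron_length_range` unless given explicitly.
#'
#' @param phase_vector Integer vector over `{0,1,2}` (may be empty for a
#'   single-exon gene).
#' @param intron_lengths Optional integer vector (one per intron).
#' @param gene_id Gene identifier.
#' @param strand `"+"` or `"-"`.
#' @param seed Integer RNG seed.
#' @param intron_length_range Range introns are drawn from.
#' @return List with `model` (a [gene_model]) and `truth` (the requested
#'   phase vector).
#' @export
make_gene_model <- function(phase_vector, intron_lengths = NULL,
                            gene_id = "syngene", strand = "+", seed = 1L,
                            intron_length_range = c(60L, 200L)) {
  phase_vector <- as.integer(phase_vector)
  if (length(phase_vector) && !all(phase_vector %in% 0:2)) {
    stop_cesafam("bad_phase", "phases must be 0, 1 or 2")
  }
  set.seed(seed)
  n_exons <- length(phase_vector) + 1L
  # residue each exon's length must contribute mod 3
  prev <- c(0L, phase_vector)
  target_mod <- c((phase_vector - prev[-length(prev)]) %% 3L,
                  (0L - prev[length(prev)]) %% 3L)
  exon_len <- 3L * sample(10:60, n_exons, replace = TRUE) + target_mod
  if (is.null(intron_lengths)) {
    intron_lengths <- sample(intron_length_range[1]:intron_length_range[2],
                             max(n_exons - 1L, 0L), replace = TRUE)
  }
  stopifnot(length(intron_lengths) == n_exons - 1L)
  starts <- integer(n_exons)
  pos <- 0L
  exons <- matrix(0L, n_exons, 2L, dimnames = list(NULL, c("start", "end")))
  for (i in seq_len(n_exons)) {
    exons[i, ] <- c(pos, pos + exon_len[i])
    pos <- pos + exon_len[i] + if (i < n_exons) intron_lengths[i] else 0L
  }
  if (strand == "-") {
    # mirror the coordinates so translation order runs descending
    total <- max(exons[, "end"])
    exons <- cbind(start = total - exons[, "end"], end = total - exons[, "start"])
  }
  model <- gene_model(gene_id, strand, exons)
  list(model = model, truth = list(phases = phase_vector))
}

#' Generate a two-group negative-binomial count matrix
#'
#' Emulates an organ-by-stage RNA-seq design with a secondary-wall gene
#' group strongly elevated in mature stem samples and a primary-wall group
#' elevated in the remaining (growing) tissues. Counts are negative
#' binomial with dispersion `dispersion` (variance mu + dispersion*mu^2).
#'
#' @param n_scw_genes,n_pcw_genes Group sizes (defaults 7 and 14, the
#'   wheat family's heat-map composition).
#' @param samples Data frame with columns `organ`, `stage`; defaults to a
#'   five-organ, three-stage design with mature-stem samples flagged.
#' @param scw_samples Logical vector, one per sample: which samples are
#'   mature-stem-like (SCW-favoring). Default: stem at 2-nodes/anthesis.
#' @param base_mean Baseline negative-binomial mean.
#' @param scw_fold Fold-elevation of SCW genes in mature-stem samples
#'   (default 10).
#' @param pcw_fold Fold-elevation of PCW genes elsewhere (default 5).
#' @param dispersion NB dispersion (default 0.1); 0 gives Poisson.
#' @param seed Integer RNG seed.
#' @return List with `counts` (a `counts_matrix`) and `truth` (gene group
#'   labels, sample design, parameters).
#' @export
make_counts <- function(n_scw_genes = 7L, n_pcw_genes = 14L,
                        samples = NULL, scw_samples = NULL,
                        base_mean = 100, scw_fold = 10, pcw_fold = 5,
                        dispersion = 0.1, seed = 7L) {
  if (is.null(samples)) {
    samples <- data.frame(
      organ = rep(c("root", "leaf", "stem", "spike", "grain"), each = 3L),
      stage = c("seedling", "three_leaves", "meiosis",
                "seedling", "three_tillers", "2daa",
                "spike_1cm", "2nodes", "anthesis",
                "2nodes", "meiosis", "anthesis",
                "2daa", "14daa", "30daa"),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(scw_samples)) {
    scw_samples <- samples$organ == "stem" & samples$stage %in% c("2nodes", "anthesis")
  }
  stopifnot(length(scw_samples) == nrow(samples))
  if (!any(scw_samples) || !any(!scw_samples)) {
    stop_cesafam("bad_design",
                 "need at least one mature-stem sample and one PCW-favoring sample")
  }
  set.seed(seed)
  sample_ids <- paste(samples$organ, samples$stage, sep = "_")
  gene_ids <- c(sprintf("SCW_g%02d", seq_len(n_scw_genes)),
                sprintf("PCW_g%02d", seq_len(n_pcw_genes)))
  group <- rep(c("SCW", "PCW"), c(n_scw_genes, n_pcw_genes))
  mu <- matrix(base_mean, length(gene_ids), length(sample_ids),
               dimnames = list(gene_ids, sample_ids))
  mu[group == "SCW", scw_samples] <- base_mean * scw_fold
  mu[group == "PCW", !scw_samples] <- base_mean * pcw_fold
  draw <- if (dispersion > 0) {
    function(m) stats::rnbinom(length(m), mu = m, size = 1 / dispersion)
  } else {
    function(m) stats::rpois(length(m), m)
  }
  counts <- matrix(draw(mu), nrow(mu), ncol(mu), dimnames = dimnames(mu))
  list(
    counts = counts_matrix(counts),
    truth = list(group = stats::setNames(group, gene_ids),
                 scw_samples = stats::setNames(scw_samples, sample_ids),
                 design = samples,
                 params = list(base_mean = base_mean, scw_fold = scw_fold,
                               pcw_fold = pcw_fold, dispersion = dispersion,
                               seed = seed))
  )
}

#' Generate the standard nine-protein demonstration panel
#'
#' Three PCW proteins and two of each SCW ortholog type (CesA4-, CesA7-
#' and CesA8-like), with seeds derived from `seed`.
#'
#' @param seed Base seed.
#' @return List with `proteins` (list of [protein_record]) and `truths`.
#' @export
make_protein_panel <- function(seed = 1L) {
  specs <- list(
    list("PCW", "PCW-type"), list("PCW", "PCW-type"), list("PCW", "PCW-type"),
    list("SCW", "CesA4-like"), list("SCW", "CesA4-like"),
    list("SCW", "CesA7-like"), list("SCW", "CesA7-like"),
    list("SCW", "CesA8-like"), list("SCW", "CesA8-like")
  )
  out <- lapply(seq_along(specs), function(i) {
    tmpl <- cesa_template(specs[[i]][[1]], specs[[i]][[2]],
                          seed = seed * 1000L + i)
    g <- make_cesa_protein(tmpl)
    g$protein$id <- sprintf("panel%02d_%s", i, g$protein$id)
    g
  })
  list(proteins = lapply(out, `[[`, "protein"),
       truths = lapply(out, `[[`, "truth"))
}
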