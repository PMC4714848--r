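# Distance phylogenetics: complete gap deletion, Poisson-corrected
# amino-acid distances, Saitou-Nei neighbor joining with deterministic
# tie-breaking, and column bootstrap with support mapping onto the
# full-data tree. Trees are ape "phylo" objects throughout.

GAP_CHARS <- c("-", ".", "?")

#' Remove alignment columns with gaps or missing data
#'
#' Complete-deletion filtering: every column containing a gap character or
#' a non-canonical (ambiguity) letter in any row is removed.
#'
#' @param aln An `alignment` matrix (see [alignment_matrix()]).
#' @return The reduced alignment; attribute `removed_columns` records how
#'   many columns were dropped.
#' @export
complete_deletion <- function(aln) {
  m <- unclass(aln)
  keep <- apply(m, 2L, function(col) all(col %in% AA_CANONICAL))
  if (!any(keep)) {
    stop_cesafam("no_columns", "complete deletion removed every column")
  }
  out <- m[, keep, drop = FALSE]
  class(out) <- c("alignment", class(out))
  attr(out, "removed_columns") <- sum(!keep)
  out
}

#' Pairwise p-distances of an alignment
#'
#' Proportion of differing sites per sequence pair. Assumes gap/missing
#' columns were already removed (see [complete_deletion()]).
#'
#' @param aln An `alignment` matrix.
#' @return Symmetric numeric matrix of p-distances, zero diagonal.
#' @export
p_distance <- function(aln) {
  m <- unclass(aln)
  n <- nrow(m)
  L <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        p <- sum(m[i, ] != m[j, ]) / L
        d[i, j] <- d[j, i] <- p
      }
    }
  }
  d
}

#' Poisson-corrected amino-acid distances
#'
#' Corrects p-distances for multiple hits under the Poisson model of equal
#' substitution rates across sites: `d = -ln(1 - p)`.
#'
#' @param aln An `alignment` matrix (apply [complete_deletion()] first).
#' @return Symmetric matrix of corrected distances with attribute `p`
#'   holding the underlying p-distance matrix and attribute
#'   `kind = "poisson"`.
#' @export
poisson_distance <- function(aln) {
  p <- p_distance(aln)
  if (any(p >= 1)) {
    stop_cesafam("saturated_distance",
                 "p-distance of 1 between some pair: Poisson correction undefined")
  }
  d <- -log(1 - p)
  attr(d, "p") <- p
  attr(d, "kind") <- "poisson"
  d
}

# Quote a Newick label if it contains metacharacters.
newick_label <- function(x) {
  ifelse(grepl("[](),:;'[[:space:]]]|\\[", x),
         paste0("'", gsub("'", "''", x), "'"),
         x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomerative algorithm: repeatedly join the pair
#' minimizing the Q criterion, with ties broken by the smallest
#' (row, column) index pair in the current matrix, until three nodes
#' remain, then close the unrooted tree with the three-taxon closed-form
#' branch lengths. Negative branch-length estimates are clamped to zero
#' and the total clamped deficit recorded.
#'
#' @param dist Symmetric numeric distance matrix with dimnames (ids).
#' @return An unrooted `ape::phylo` tree (basal trifurcation); attribute
#'   `clamped_deficit` records the summed magnitude of negative branch
#'   estimates clamped to zero.
#' @export
nj_tree <- function(dist) {
  d <- unclass(dist)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12))) {
    stop_cesafam("asymmetric_distances", "distance matrix is not symmetric")
  }
  ids <- rownames(d)
  n <- nrow(d)
  if (n < 3L) {
    stop_cesafam("too_few_taxa", "neighbor joining needs at least 3 taxa")
  }
  clamp_deficit <- 0
  clamp <- function(x) {
    if (x < 0) {
      clamp_deficit <<- clamp_deficit - x
      0
    } else x
  }
  # full precision in the internal Newick assembly; file output rounds later
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  labels <- newick_label(ids)

  while (n > 3L) {
    R <- rowSums(d)
    # Q criterion; only the upper triangle is searched, row-major, so the
    # first minimum encountered is the smallest (row, column) pair
    best <- NULL
    best_q <- Inf
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        q <- (n - 2) * d[i, j] - R[i] - R[j]
        if (q < best_q - 1e-12) {
          best_q <- q
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    vi <- clamp(d[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2)))
    vj <- clamp(d[i, j] - (d[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))))
    new_label <- sprintf("(%s:%s,%s:%s)", labels[i], fmt(vi), labels[j], fmt(vj))
    duk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d_new <- rbind(cbind(d[keep, keep, drop = FALSE], duk[keep]),
                   c(duk[keep], 0))
    labels <- c(labels[keep], new_label)
    rownames(d_new) <- colnames(d_new) <- NULL
    d <- d_new
    n <- n - 1L
  }
  va <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  vb <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  vc <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    labels[1], fmt(va), labels[2], fmt(vb), labels[3], fmt(vc))
  tree <- ape::read.tree(text = newick)
  attr(tree, "clamped_deficit") <- clamp_deficit
  tree
}

# Canonical bipartition keys for the internal edges of an unrooted tree
# stored as a basally trifurcating phylo: each non-root internal node's
# clade, expressed as the tip-label side NOT containing `ref`, sorted and
# collapsed to one string.
tree_bipartitions <- function(phy, ref = NULL) {
  tips <- phy$tip.label
  if (is.null(ref)) ref <- sort(tips)[1]
  n_tip <- length(tips)
  internal <- setdiff(unique(phy$edge[, 1]), n_tip + 1L)  # exclude root
  vapply(internal, function(node) {
    clade <- ape::extract.clade(phy, node)$tip.label
    side <- if (ref %in% clade) setdiff(tips, clade) else clade
    paste(sort(side), collapse = "|")
  }, "")
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the full-data tree (complete deletion, Poisson correction, NJ),
#' then resamples alignment columns with replacement per replicate, rebuilds
#' a tree per replicate the same way, and reports for each internal edge of
#' the full-data tree the percentage of replicates whose tree contains the
#' same bipartition. Replicates in which the Poisson distance is undefined
#' (a saturated pair) or no column survives deletion are skipped and
#' counted; more than 50% skipped is an error.
#'
#' @param aln An `alignment` matrix.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the resampling RNG.
#' @return The full-data `ape::phylo` tree with integer percentage supports
#'   in `node.label` (root label empty) and attributes `supports` (named by
#'   bipartition) and `skipped_replicates`.
#' @export
bootstrap_nj <- function(aln, replicates = 1000L, seed = 1L) {
  stopifnot(replicates >= 1L)
  reduced <- complete_deletion(aln)
  full_tree <- nj_tree(poisson_distance(reduced))
  ref <- sort(rownames(aln))[1]
  full_bip <- tree_bipartitions(full_tree, ref)
  counts <- stats::setNames(numeric(length(full_bip)), full_bip)
  skipped <- 0L
  set.seed(seed)
  L <- ncol(aln)
  for (r in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- unclass(aln)[, cols, drop = FALSE]
    class(rep_aln) <- c("alignment", class(rep_aln))
    rep_tree <- tryCatch({
      nj_tree(poisson_distance(complete_deletion(rep_aln)))
    }, cesafam_error = function(e) NULL)
    if (is.null(rep_tree)) {
      skipped <- skipped + 1L
      next
    }
    rep_bip <- tree_bipartitions(rep_tree, ref)
    hit <- full_bip %in% rep_bip
    counts[hit] <- counts[hit] + 1
  }
  if (skipped > replicates / 2) {
    stop_cesafam("bootstrap_degenerate",
                 sprintf("%d of %d bootstrap replicates unusable", skipped, replicates))
  }
  effective <- replicates - skipped
  supports <- round(100 * counts / effective)
  # map supports onto node labels (internal nodes in the order used above)
  n_tip <- length(full_tree$tip.label)
  internal <- setdiff(unique(full_tree$edge[, 1]), n_tip + 1L)
  node_label <- character(full_tree$Nnode)
  node_label[internal - n_tip] <- as.character(supports)
  full_tree$node.label <- node_label
  attr(full_tree, "supports") <- supports
  attr(full_tree, "skipped_replicates") <- skipped
  full_tree
}

#' Bootstrap support of a given bipartition
#'
#' Looks up the support of the bipartition separating `tips` from the rest
#' in a tree produced by [bootstrap_nj()].
#'
#' @param tree Tree returned by [bootstrap_nj()].
#' @param tips Character vector of tip labels on one side of the split.
#' @return Integer percentage support, or `NA` if the full-data tree does
#'   not contain that bipartition.
#' @export
clade_support <- function(tree, tips) {
  supports <- attr(tree, "supports")
  if (is.null(supports)) {
    stop_cesafam("no_supports", "tree carries no bootstrap supports")
  }
  all_tips <- tree$tip.label
  ref <- sort(all_tips)[1]
  side <- if (ref %in% tips) setdiff(all_tips, tips) else tips
  key <- paste(sort(side), collapse = "|")
  if (key %in% names(supports)) unname(supports[[key]]) else NA_integer_
}

#' Write a tree in Newick format
#'
#' Branch lengths are kept at 6 significant digits; bootstrap supports (if
#' present) are written as internal node labels.
#'
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An `ape::phylo`.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Write a distance matrix in PHYLIP square format
#' @param dist Symmetric distance matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(dist, path) {
  ids <- rownames(dist)
  lines <- c(sprintf("%5d", nrow(dist)),
             vapply(seq_len(nrow(dist)), function(i) {
               paste0(formatC(ids[i], width = -10),
                      paste(formatC(dist[i, ], digits = 6, format = "f"),
                            collapse = "  "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
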