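# Expression stage: counts-per-million normalization, log2 transform with
# pseudocount, per-gene z-scoring, and agglomerative Ward clustering on
# Pearson correlation distances (the heat-map pipeline).

#' Counts per million
#'
#' Library-size normalization: each count is divided by its sample's total
#' and scaled to one million.
#'
#' @param counts A `counts_matrix` (or plain non-negative matrix with
#'   dimnames).
#' @return Numeric matrix of CPM values with attribute `stage = "cpm"`.
#' @export
cpm <- function(counts) {
  m <- unclass(counts)
  libs <- colSums(m)
  if (any(libs <= 0)) {
    stop_cesafam("zero_library", "a sample has zero library size")
  }
  out <- sweep(m, 2L, libs, "/") * 1e6
  attr(out, "stage") <- "cpm"
  out
}

#' Log2-transformed CPM
#'
#' `log2(CPM + pseudocount)`; the pseudocount (default 0.5) keeps zero
#' counts finite.
#'
#' @param expr CPM matrix from [cpm()].
#' @param pseudocount Added before the log, default 0.5.
#' @return Matrix with attribute `stage = "log2_cpm"`.
#' @export
log2_cpm <- function(expr, pseudocount = 0.5) {
  out <- log2(unclass(expr) + pseudocount)
  attr(out, "stage") <- "log2_cpm"
  out
}

#' Per-gene z-scores
#'
#' Centers and scales each row to mean 0 and standard deviation 1, using
#' the population (divide-by-n) standard deviation. Rows with zero
#' variance cannot be scaled; they are flagged and dropped.
#'
#' @param expr Expression matrix (genes in rows).
#' @return Z-scored matrix with attributes `stage = "zscore"` and
#'   `dropped_constant` (character vector of flagged gene ids).
#' @export
zscore_rows <- function(expr) {
  m <- unclass(expr)
  mu <- rowMeans(m)
  sdp <- sqrt(rowMeans((m - mu)^2))       # population sd
  constant <- sdp == 0
  if (any(constant)) {
    warning(sprintf("dropping %d constant gene(s): %s", sum(constant),
                    paste(rownames(m)[constant], collapse = ", ")))
  }
  out <- (m[!constant, , drop = FALSE] - mu[!constant]) / sdp[!constant]
  attr(out, "stage") <- "zscore"
  attr(out, "dropped_constant") <- rownames(m)[constant]
  out
}

#' Ward clustering on Pearson correlation distances
#'
#' Distance between items is `1 - r` (Pearson correlation), clustered with
#' Ward's minimum-variance criterion (`ward.D2`, i.e. the squared-distance
#' update). Items with zero variance (undefined correlation) are dropped
#' with a warning. `stats::hclust` resolves merge ties by item index, so
#' the result is deterministic.
#'
#' @param expr Numeric matrix.
#' @param axis `"genes"` to cluster rows (default) or `"samples"` for
#'   columns.
#' @return An `hclust` object; `attr(, "dropped")` lists items dropped for
#'   zero variance.
#' @export
pearson_ward <- function(expr, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  m <- unclass(expr)
  if (axis == "samples") m <- t(m)
  v <- apply(m, 1L, stats::var)
  dropped <- rownames(m)[v == 0 | is.na(v)]
  if (length(dropped)) {
    warning(sprintf("dropping %d zero-variance item(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    m <- m[!(rownames(m) %in% dropped), , drop = FALSE]
  }
  if (nrow(m) < 2L) {
    stop_cesafam("too_few_items", "need at least 2 items with nonzero variance")
  }
  d <- stats::as.dist(1 - stats::cor(t(m)))
  hc <- stats::hclust(d, method = "ward.D2")
  attr(hc, "dropped") <- dropped
  hc
}

#' Two-group cut of a dendrogram
#'
#' Convenience wrapper around [stats::cutree()] for the top-level split.
#'
#' @param hc An `hclust`.
#' @param k Number of groups, default 2.
#' @return Named integer vector of group memberships.
#' @export
top_split <- function(hc, k = 2L) {
  stats::cutree(hc, k = k)
}

#' Build the ordered heat-map matrix
#'
#' Runs the full pipeline counts -> CPM -> log2 -> scaling, then clusters
#' genes and samples (Ward on Pearson distances) and returns the scaled
#' matrix reordered by the two dendrograms' leaf orders. Scaling is
#' per-gene z-scores by default; `scaling = "global"` instead centers and
#' scales the whole log2-CPM matrix by its grand mean and population sd,
#' preserving between-gene magnitude.
#'
#' @param counts A `counts_matrix`.
#' @param cluster_samples Also cluster and reorder columns (default TRUE).
#' @param scaling `"row"` (per-gene z-scores, default) or `"global"`.
#' @return List with `matrix` (ordered, scaled), `gene_hclust`,
#'   `sample_hclust` (or `NULL`).
#' @export
heatmap_matrix <- function(counts, cluster_samples = TRUE,
                           scaling = c("row", "global")) {
  scaling <- match.arg(scaling)
  lc <- log2_cpm(cpm(counts))
  z <- if (scaling == "row") {
    zscore_rows(lc)
  } else {
    m <- unclass(lc)
    out <- (m - mean(m)) / sqrt(mean((m - mean(m))^2))
    attr(out, "stage") <- "global_zscore"
    out
  }
  gh <- pearson_ward(z, "genes")
  sh <- if (cluster_samples && ncol(z) >= 2L) {
    tryCatch(pearson_ward(z, "samples"), cesafam_error = function(e) NULL)
  } else NULL
  m <- unclass(z)[gh$order, , drop = FALSE]
  if (!is.null(sh)) m <- m[, sh$order, drop = FALSE]
  list(matrix = m, gene_hclust = gh, sample_hclust = sh)
}

# hclust -> dendrogram-as-Newick (leaf names, merge heights as branch
# lengths), for the report files.
hclust_newick <- function(hc) {
  n <- length(hc$labels)
  frag <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%s", newick_label(hc$labels[-i]), formatC(parent_h, digits = 6, format = "g"))
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%s",
              frag(hc$merge[i, 1], h), frag(hc$merge[i, 2], h),
              formatC(parent_h - h, digits = 6, format = "g"))
    }
  }
  top <- length(hc$height)
  h <- hc$height[top]
  sprintf("(%s,%s);", frag(hc$merge[top, 1], h), frag(hc$merge[top, 2], h))
}
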