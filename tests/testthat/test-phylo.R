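aln_from_rows <- function(...) alignment_matrix(c(...), paste0("s", seq_along(c(...))))

test_that("complete deletion removes every column with a gap or ambiguity", {
  red <- complete_deletion(aln_from_rows("AC-G", "AC-G"))
  expect_equal(apply(unclass(red), 1, paste0, collapse = ""),
               c(s1 = "ACG", s2 = "ACG"))
  expect_equal(attr(red, "removed_columns"), 1L)

  clean <- aln_from_rows("ACDE", "ACDF")
  expect_equal(unclass(complete_deletion(clean))[, ], unclass(clean)[, ])

  red <- complete_deletion(aln_from_rows("A-", "AA"))
  expect_equal(ncol(red), 1L)
  # ambiguity letters count as missing data
  red <- complete_deletion(aln_from_rows("AXG", "AAG"))
  expect_equal(ncol(red), 2L)
  expect_error(complete_deletion(aln_from_rows("-A", "A-")),
               class = "cesafam_no_columns")
})

test_that("Poisson correction matches the closed form and bounds p below", {
  identical_rows <- aln_from_rows("ACDEF", "ACDEF")
  expect_equal(unname(poisson_distance(identical_rows)[1, 2]), 0)

  half <- aln_from_rows("AAAA", "AAGG")      # p = 0.5
  d <- poisson_distance(half)
  expect_equal(unname(d[1, 2]), log(2), tolerance = 1e-12)

  set.seed(3)
  for (rep in 1:20) {
    L <- 40
    a <- paste0(sample(cesafam:::AA_CANONICAL, L, TRUE), collapse = "")
    b <- strsplit(a, "")[[1]]
    flip <- sample(L, sample(0:(L - 1), 1))
    b[flip] <- vapply(b[flip], function(x) sample(setdiff(LETTERS[1:4], x), 1), "")
    aln <- alignment_matrix(c(a, paste0(b, collapse = "")), c("x", "y"))
    aln <- complete_deletion(aln)   # drops columns where flip made ambiguity
    d <- poisson_distance(aln)
    p <- attr(d, "p")
    expect_true(all(d >= p))
    expect_equal(d[1, 2] == p[1, 2], p[1, 2] == 0)
  }

  saturated <- aln_from_rows("AAAA", "GGGG")
  expect_error(poisson_distance(saturated), class = "cesafam_saturated_distance")
})

test_that("three-taxon neighbor joining gives the closed-form star", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["a"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["b"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["c"]], (4 + 5 - 3) / 2)
  expect_error(nj_tree(matrix(c(0, 1, 1, 0), 2,
                              dimnames = list(c("a", "b"), c("a", "b")))),
               class = "cesafam_too_few_taxa")
  asym <- d; asym[1, 2] <- 9
  expect_error(nj_tree(asym), class = "cesafam_asymmetric_distances")
})

test_that("NJ recovers random additive trees exactly, matching ape", {
  skip_if_not_installed("phangorn")
  set.seed(10)
  for (rep in 1:15) {
    n <- sample(5:8, 1)
    true <- ape::rtree(n, rooted = FALSE,
                       br = function(k) stats::runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(true)
    d <- d[sort(rownames(d)), sort(rownames(d))]
    est <- nj_tree(d)
    expect_equal(phangorn::RF.dist(ape::unroot(true), est), 0)
    expect_lt(max(abs(ape::cophenetic.phylo(est)[rownames(d), colnames(d)] - d)),
              1e-9)
    # independent cross-check: ape's NJ agrees on topology
    expect_equal(phangorn::RF.dist(ape::nj(d), est), 0)
  }
})

test_that("equal-distance matrices give a deterministic tie-broken tree", {
  d <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(d) <- 0
  t1 <- nj_tree(d)
  t2 <- nj_tree(d)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("negative branch estimates are clamped with the deficit recorded", {
  # a non-additive matrix known to force a negative limb estimate
  d <- matrix(c(0.000, 0.604, 0.807, 1.826,
                0.604, 0.000, 1.188, 0.483,
                0.807, 1.188, 0.000, 1.807,
                1.826, 0.483, 1.807, 0.000), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  expect_gt(attr(tr, "clamped_deficit"), 0)
})

test_that("bootstrap supports are reproducible, bounded, and saturate on clean splits", {
  # twenty columns support the same 2-vs-2 split; constant columns keep
  # every pairwise p-distance below saturation
  m <- cbind(
    matrix(rep(c("A", "A", "G", "G"), 20), nrow = 4),
    c("A", "C", "G", "G"),       # separates t1 from t2
    c("A", "A", "G", "W"),       # separates t3 from t4
    matrix("P", 4, 8)
  )
  rownames(m) <- paste0("t", 1:4)
  class(m) <- c("alignment", class(m))
  tr <- bootstrap_nj(m, replicates = 25, seed = 5)
  expect_equal(clade_support(tr, c("t1", "t2")), 100)

  # determinism contract: same seed, same supports
  tr2 <- bootstrap_nj(m, replicates = 25, seed = 5)
  expect_identical(attr(tr, "supports"), attr(tr2, "supports"))

  # a single replicate can only yield 0 or 100
  tr1 <- bootstrap_nj(m, replicates = 1, seed = 9)
  expect_true(all(attr(tr1, "supports") %in% c(0, 100)))
})

test_that("bootstrap supports are invariant under leaf relabeling", {
  fam <- showcase_family(seed = 7, ortholog_branch = 0.3)
  aln <- fam$alignment
  tr <- bootstrap_nj(aln, replicates = 20, seed = 3)
  perm <- unclass(aln)[rev(seq_len(nrow(aln))), , drop = FALSE]
  class(perm) <- c("alignment", class(perm))
  tr_perm <- bootstrap_nj(perm, replicates = 20, seed = 3)
  for (grp in unique(fam$groups)) {
    tips <- names(fam$groups)[fam$groups == grp]
    expect_equal(clade_support(tr_perm, tips), clade_support(tr, tips))
  }
})

test_that("Newick output round-trips trees", {
  set.seed(13)
  for (seed in 1:3) {
    tr <- ape::rtree(6, rooted = FALSE)
    f <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, f)
    back <- read_newick(f)
    expect_equal(sort(back$tip.label), sort(tr$tip.label))
    expect_equal(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label],
                 ape::cophenetic.phylo(tr),
                 tolerance = 1e-5)
  }
})
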