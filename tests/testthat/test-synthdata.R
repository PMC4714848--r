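test_that("template validation enforces class/type/variant consistency", {
  expect_error(cesa_template("PCW", "CesA4-like"), class = "cesafam_bad_template")
  expect_error(cesa_template("SCW", "PCW-type"), class = "cesafam_bad_template")
  expect_error(cesa_template("SCW", "CesA7-like", znf_variant = "full_46"),
               class = "cesafam_bad_template")
  expect_equal(cesa_template("SCW", "CesA7-like")$znf_variant, "deleted_38")
  expect_error(
    make_cesa_protein(cesa_template("PCW", target_length = 200, seed = 1)),
    class = "cesafam_target_too_small"
  )
})

test_that("generated proteins round-trip through the detectors", {
  for (seed in c(1, 8)) {
    for (spec in list(c("PCW", "PCW-type"), c("SCW", "CesA4-like"),
                      c("SCW", "CesA7-like"), c("SCW", "CesA8-like"))) {
      g <- make_cesa_protein(cesa_template(spec[1], spec[2], seed = seed))
      z <- detect_znf(g$protein)
      expect_equal(z$variant, g$truth$znf_variant)
      expect_equal(z$hit$start, g$truth$znf_start)
      cc <- detect_catalytic(g$protein)
      expect_true(cc$present)
      expect_equal(c(cc$d1, cc$d2, cc$d3, cc$qxxrw),
                   c(g$truth$d1, g$truth$d2, g$truth$d3, g$truth$qxxrw))
      wc <- classify_wall(g$protein)
      expect_equal(wc$call, spec[1])
      expect_equal(wc$ortholog_hint, spec[2])
      # length lands in the class-typical range
      rng <- if (spec[1] == "PCW") 1075:1091 else 991:1055
      expect_true(g$truth$length %in% rng)
    }
  }
})

test_that("generation is seed-deterministic down to bytes on disk", {
  g1 <- make_cesa_protein(cesa_template("PCW", seed = 77))
  g2 <- make_cesa_protein(cesa_template("PCW", seed = 77))
  expect_identical(g1, g2)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(list(g1$protein), f1)
  write_fasta(list(g2$protein), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(
    g1$protein$sequence,
    make_cesa_protein(cesa_template("PCW", seed = 78))$protein$sequence
  ))
})

test_that("zero-length branches copy the parent; protection freezes motifs", {
  g <- make_cesa_protein(cesa_template("SCW", "CesA8-like", seed = 2))
  tree <- ape::read.tree(text = "((a:0,b:0.4):0.1,(c:0.3,d:0.3):0.1,e:0.5);")
  aln <- evolve_family(g$protein, tree,
                       protect = protected_positions(g$truth), seed = 11)
  root_chars <- strsplit(g$protein$sequence, "")[[1]]
  # a sits at the end of a path with one mutated internal branch; its
  # terminal branch of length 0 must add nothing beyond the internal edge
  expect_equal(nrow(unclass(aln)), 5L)
  # every leaf keeps the diagnostic motifs, hence the classification
  for (tip in rownames(aln)) {
    p <- protein_record(tip, paste0(unclass(aln)[tip, ], collapse = ""))
    wc <- classify_wall(p)
    expect_equal(wc$call, "SCW")
    expect_equal(wc$ortholog_hint, "CesA8-like")
  }
  # a truly zero path: single cherry with both branches 0
  tree0 <- ape::read.tree(text = "(x:0,y:0,z:0.2);")
  aln0 <- evolve_family(g$protein, tree0, seed = 5)
  expect_equal(paste0(unclass(aln0)["x", ], collapse = ""), g$protein$sequence)
  expect_equal(paste0(unclass(aln0)["y", ], collapse = ""), g$protein$sequence)
})

test_that("leaf divergence matches the replacement-process closed form", {
  # two leaves at total separation t: P(site differs) for a rate-t uniform
  # replacement process over 19 alternatives is (19/20)(1 - exp(-20 t / 19))
  g <- make_cesa_protein(cesa_template("PCW", seed = 13))
  L <- nchar(g$protein$sequence)
  for (t_total in c(0.2, 0.8)) {
    tree <- ape::read.tree(
      text = sprintf("(a:%f,b:%f,c:0.01);", t_total / 2, t_total / 2))
    aln <- evolve_family(g$protein, tree, seed = 31)
    p_obs <- sum(unclass(aln)["a", ] != unclass(aln)["b", ]) / L
    p_exp <- (19 / 20) * (1 - exp(-20 * t_total / 19))
    expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / L))
  }
})

test_that("gene-model generation realizes any requested phase vector", {
  req <- c(1L, 0L, 1L, 2L, 0L, 0L, 0L)
  gm <- make_gene_model(req, seed = 4)
  expect_equal(as.integer(intron_phases(gm$model)), req)
  expect_true(all(exon_lengths(gm$model) >= 30))
  expect_equal(sum(exon_lengths(gm$model)) %% 3, 0)

  # empty request: single-exon gene
  gm0 <- make_gene_model(integer(0), seed = 1)
  expect_equal(nrow(gm0$model$coding_exons), 1L)
  expect_length(intron_phases(gm0$model), 0L)

  set.seed(90)
  for (rep in 1:200) {
    req <- sample(0:2, sample(0:14, 1), replace = TRUE)
    gm <- make_gene_model(req, seed = rep, strand = sample(c("+", "-"), 1))
    expect_equal(as.integer(intron_phases(gm$model)), as.integer(req))
  }
  expect_error(make_gene_model(c(0, 3)), class = "cesafam_bad_phase")
})

test_that("two-group counts carry the designed structure and labels", {
  mc <- make_counts(seed = 7)
  m <- unclass(mc$counts)
  expect_true(all(m >= 0) && all(m == floor(m)) && all(is.finite(m)))
  expect_equal(dim(m), c(21L, 15L))
  truth <- mc$truth
  expect_equal(sum(truth$group == "SCW"), 7L)
  expect_equal(sum(truth$scw_samples), 2L)
  # SCW genes dominate in mature-stem samples, PCW elsewhere
  scw_mean <- mean(m[truth$group == "SCW", truth$scw_samples])
  pcw_mean <- mean(m[truth$group == "PCW", truth$scw_samples])
  expect_gt(scw_mean, 3 * pcw_mean)
  expect_error(
    make_counts(scw_samples = rep(FALSE, 15)),
    class = "cesafam_bad_design"
  )
  # byte-identical TSV under the same seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_counts(make_counts(seed = 9)$counts, f1)
  write_counts(make_counts(seed = 9)$counts, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the showcase family keeps its motifs and its clade structure", {
  fam <- showcase_family(seed = 42)
  expect_equal(nrow(unclass(fam$alignment)), 9L)
  expect_equal(sort(unique(unname(fam$groups))), c("CesA4", "CesA7", "CesA8"))
  # generating tree and alignment rows agree
  expect_setequal(rownames(fam$alignment), fam$tree$tip.label)
  # within-clade distances are smaller than between-clade distances
  d <- p_distance(complete_deletion(fam$alignment))
  same <- outer(fam$groups[rownames(d)], fam$groups[colnames(d)], "==")
  diag(same) <- NA
  expect_lt(max(d[which(same)]), min(d[which(!same)]))
})
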