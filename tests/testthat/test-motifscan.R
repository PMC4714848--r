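test_that("pattern compilation yields the documented lengths", {
  expect_equal(compile_pattern("CX2-CX14-ACX2-CX4-CX2-CX7-GX3-CX2-C")$length, 46L)
  expect_equal(compile_pattern("CX2-CX6-ACX2-CX4-CX2-CX7-GX3-CX2-C")$length, 38L)
  qp <- compile_pattern("QXXRW")
  expect_equal(qp$length, 5L)
  expect_equal(
    vapply(qp$elements, function(e) if (e$type == "fixed") e$residue else "X", ""),
    c("Q", "X", "X", "R", "W")
  )
  # bare X is a run of one; parentheses and separators ignored
  expect_equal(compile_pattern("(CXXC)")$length, 4L)
})

test_that("pattern length is additive over concatenated specs", {
  specs <- c("CX2C", "QXXRW", "SXXCEXWF", "ACX4", "GX3CX2C")
  for (a in specs) for (b in specs) {
    expect_equal(compile_pattern(paste0(a, b))$length,
                 compile_pattern(a)$length + compile_pattern(b)$length)
  }
})

test_that("compilation rejects illegal characters and zero repeats", {
  err <- expect_error(compile_pattern("CX2Z3"), class = "cesafam_bad_pattern_char")
  expect_match(conditionMessage(err), "offset")
  expect_error(compile_pattern("CX0C"), class = "cesafam_bad_repeat")
  expect_error(compile_pattern("---"), class = "cesafam_empty_pattern")
})

test_that("scanning reports all overlapping hits, left to right", {
  cxxc <- compile_pattern("CXXC")
  hits <- scan_motif("ACQICG", cxxc)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1L)
  expect_equal(hits$end, 5L)
  expect_equal(hits$matched, "CQIC")
  # wildcards may match the fixed letter itself
  expect_equal(scan_motif("CCCC", cxxc)$start, 0L)
  # overlapping occurrences all reported
  expect_equal(scan_motif("CCCCCCC", cxxc)$start, 0:3)
  expect_equal(nrow(scan_motif("AAAA", cxxc)), 0L)
})

test_that("scan agrees with the brute-force offset matcher", {
  set.seed(42)
  specs <- c("CXXC", "CX2G", "Q", "AXA", "CXGXA", "GG")
  for (rep in 1:60) {
    s <- random_protein_string(sample(1:30, 1))
    spec <- sample(specs, 1)
    got <- scan_motif(s, compile_pattern(spec))$start
    expect_identical(got, brute_force_scan(s, spec), label = paste(s, spec))
  }
})

test_that("zinc-finger detection tries full, deleted, then literature presets", {
  full <- make_cesa_protein(cesa_template("PCW", seed = 3))
  z <- detect_znf(full$protein)
  expect_equal(z$variant, "full_46")
  expect_equal(z$deletion_size, 0L)
  expect_equal(z$hit$start, full$truth$znf_start)

  del <- make_cesa_protein(cesa_template("SCW", "CesA7-like", seed = 3))
  z <- detect_znf(del$protein)
  expect_equal(z$variant, "deleted_38")
  expect_equal(z$deletion_size, 8L)

  none <- protein_record("blank", strrep("A", 200))
  expect_equal(detect_znf(none)$variant, "none")
})

test_that("with both variants present the most N-terminal hit wins", {
  set.seed(8)
  inst <- function(spec) {
    pat <- compile_pattern(spec)
    paste0(unlist(lapply(pat$elements, function(e) {
      if (e$type == "fixed") e$residue else
        sample(c("G", "S", "T", "N", "Q"), e$n, replace = TRUE)
    })), collapse = "")
  }
  full46 <- inst("CX2-CX14-ACX2-CX4-CX2-CX7-GX3-CX2-C")
  del38 <- inst("CX2-CX6-ACX2-CX4-CX2-CX7-GX3-CX2-C")
  spacer <- strrep("G", 30)
  # deleted variant upstream of a full one: full pattern's hit is not the
  # first C region, but the full preset is tried first and still matches
  p <- protein_record("both", paste0(spacer, del38, spacer, full46, spacer))
  z <- detect_znf(p)
  expect_equal(z$variant, "full_46")
  expect_equal(z$hit$start, 30L + 38L + 30L)
  # two full copies: most N-terminal reported
  p2 <- protein_record("two", paste0(spacer, full46, spacer, full46))
  expect_equal(detect_znf(p2)$hit$start, 30L)
})

test_that("catalytic signature search anchors on QXXRW and orders D1<D2<D3", {
  p <- protein_record("cat", paste0(
    strrep("G", 10), "D", strrep("G", 8), "DAD", strrep("G", 6), "D",
    strrep("G", 5), "QAARW", strrep("G", 10)
  ))
  cc <- detect_catalytic(p)
  expect_true(cc$present)
  expect_equal(cc$d1, 10L)
  expect_equal(cc$d2, 19L)
  expect_equal(cc$d3, 28L)
  expect_equal(cc$qxxrw, 34L)
  expect_true(cc$d1 < cc$d2 && cc$d2 < cc$d3 && cc$d3 < cc$qxxrw)

  expect_false(detect_catalytic(protein_record("noq", "DGDADGDGGG"))$present)
  # QXXRW present but no DXD upstream
  expect_false(detect_catalytic(protein_record("nod", "GGGGQAARWGG"))$present)
})

test_that("hydropathy caller finds isolated hydrophobic stretches only", {
  p <- protein_record("one", paste0(strrep("G", 40), strrep("I", 21), strrep("G", 40)))
  iv <- tmd_scan(p)
  expect_equal(nrow(iv), 1L)
  # the called interval covers the hydrophobic core
  expect_true(iv[1, "start"] >= 30 && iv[1, "end"] <= 71 + 10)

  expect_equal(nrow(tmd_scan(protein_record("gly", strrep("G", 100)))), 0L)
  expect_error(tmd_scan(p, window = 18L), class = "cesafam_bad_window")
  expect_error(tmd_scan(p, window = 3L), class = "cesafam_bad_window")
})

test_that("tmd intervals are disjoint, sorted, and eight for generated CESAs", {
  for (seed in c(2, 17)) {
    g <- make_cesa_protein(cesa_template("SCW", "CesA8-like", seed = seed))
    iv <- tmd_scan(g$protein)
    expect_equal(nrow(iv), 8L)
    expect_true(all(diff(iv[, "start"]) > 0))
    expect_true(all(iv[-nrow(iv), "end"] <= iv[-1, "start"]))
    cc <- detect_catalytic(g$protein)
    expect_equal(sum(iv[, "end"] <= cc$d1), 2L)       # two TMDs N-terminal
    expect_equal(sum(iv[, "start"] >= cc$qxxrw + 5L), 6L)  # six C-terminal
  }
})

test_that("motif tables parse and feed extra hits into annotation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# name\tspec\tclass", "qxxrw\tQXXRW\tcore", "cxxc\tCXXC\tznf"), f)
  pats <- read_motif_table(f)
  expect_named(pats, c("qxxrw", "cxxc"))
  expect_equal(attr(pats$cxxc, "class_tag"), "znf")
  g <- make_cesa_protein(cesa_template("PCW", seed = 5))
  ann <- annotate_domains(g$protein, pats)
  expect_true("qxxrw" %in% ann$class_motif_hits$pattern_name)
  writeLines("onefield", f)
  expect_error(read_motif_table(f), class = "cesafam_bad_motif_table")
})
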