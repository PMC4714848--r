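# Degenerate motif grammar and scanners.
#
# Patterns are PROSITE-flavoured strings of fixed residue letters and
# wildcard tokens: "X" matches any canonical residue, "X14" a run of 14
# wildcards. "-", "(", ")" and whitespace are ignored so the strings as
# printed in the CESA literature parse verbatim, e.g.
# "CX2-CX14-ACX2-CX4-CX2-CX7-GX3-CX2-C" (the 46-AA zinc-finger consensus).

# Zinc-finger presets: the wheat 46-AA consensus, the TaCESA7 8-AA deletion
# variant, and the older literature consensus.
ZNF_PATTERNS <- list(
  full_46    = "CX2-CX14-ACX2-CX4-CX2-CX7-GX3-CX2-C",
  deleted_38 = "CX2-CX6-ACX2-CX4-CX2-CX7-GX3-CX2-C",
  literature = "(CX2-CX12-FXACX2-CX2PXCX2-CXEX5-GX3-CX2C)"
)

#' Compile a degenerate motif pattern
#'
#' Parses a pattern string of fixed residues and `X`/`Xn` wildcard tokens
#' into an ordered element list. Separators (`-`), parentheses and
#' whitespace are ignored. A wildcard matches any of the 20 canonical
#' residues (never a gap).
#'
#' @param spec Pattern string, e.g. `"QXXRW"` or
#'   `"CX2-CX14-ACX2-CX4-CX2-CX7-GX3-CX2-C"`.
#' @param name Pattern name carried into hits.
#' @return An object of class `motif_pattern` with fields `name`,
#'   `elements` (list of `list(type = "fixed", residue =)` or
#'   `list(type = "wildcard", n =)`), `length` and `source_spec`.
#' @export
compile_pattern <- function(spec, name = spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  chars <- strsplit(spec, "")[[1]]
  elements <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", "(", ")") || grepl("[[:space:]]", ch)) {
      i <- i + 1L
    } else if (ch == "X") {
      j <- i + 1L
      digits <- ""
      while (j <= n && grepl("[0-9]", chars[j])) {
        digits <- paste0(digits, chars[j])
        j <- j + 1L
      }
      run <- if (nzchar(digits)) as.integer(digits) else 1L
      if (run == 0L) {
        stop_cesafam("bad_repeat",
                     sprintf("pattern '%s': repeat count 0 at offset %d", spec, i))
      }
      elements[[length(elements) + 1L]] <- list(type = "wildcard", n = run)
      i <- j
    } else if (ch %in% AA_CANONICAL) {
      elements[[length(elements) + 1L]] <- list(type = "fixed", residue = ch)
      i <- i + 1L
    } else {
      stop_cesafam("bad_pattern_char",
                   sprintf("pattern '%s': illegal character '%s' at offset %d",
                           spec, ch, i))
    }
  }
  if (!length(elements)) {
    stop_cesafam("empty_pattern", sprintf("pattern '%s' compiles to length 0", spec))
  }
  len <- sum(vapply(elements, function(e) if (e$type == "fixed") 1L else e$n, 1L))
  structure(
    list(name = name, elements = elements, length = len, source_spec = spec),
    class = "motif_pattern"
  )
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s: %s (length %d)\n", x$name, x$source_spec, x$length))
  invisible(x)
}

# Fixed-position map of a compiled pattern: offsets (0-based) and required
# residues; wildcard positions are unconstrained.
pattern_fixed_positions <- function(pattern) {
  off <- 0L
  pos <- integer(0)
  res <- character(0)
  for (e in pattern$elements) {
    if (e$type == "fixed") {
      pos <- c(pos, off)
      res <- c(res, e$residue)
      off <- off + 1L
    } else {
      off <- off + e$n
    }
  }
  list(offsets = pos, residues = res)
}

#' Scan a protein for all occurrences of a compiled pattern
#'
#' Reports every (possibly overlapping) occurrence left to right. Fixed
#' residues must match exactly; wildcards match any canonical residue.
#'
#' @param protein A [protein_record] (or a bare sequence string).
#' @param pattern A compiled [motif_pattern].
#' @return Data frame of hits with columns `pattern_name`, `start`, `end`
#'   (0-based half-open) and `matched`; zero rows when nothing matches.
#' @export
scan_motif <- function(protein, pattern) {
  seq <- if (inherits(protein, "protein_record")) protein$sequence else protein
  stopifnot(inherits(pattern, "motif_pattern"))
  L <- nchar(seq)
  k <- pattern$length
  empty <- data.frame(pattern_name = character(0), start = integer(0),
                      end = integer(0), matched = character(0),
                      stringsAsFactors = FALSE)
  if (k > L) return(empty)
  fx <- pattern_fixed_positions(pattern)
  chars <- strsplit(seq, "")[[1]]
  starts0 <- 0:(L - k)
  ok <- rep(TRUE, length(starts0))
  for (i in seq_along(fx$offsets)) {
    ok <- ok & chars[starts0 + fx$offsets[i] + 1L] == fx$residues[i]
  }
  hits <- starts0[ok]
  if (!length(hits)) return(empty)
  data.frame(
    pattern_name = pattern$name,
    start = hits,
    end = hits + k,
    matched = substring(seq, hits + 1L, hits + k),
    stringsAsFactors = FALSE
  )
}

#' Locate the zinc-finger (RING-like) domain
#'
#' Tries the 46-AA wheat consensus first, then the 8-AA deletion variant
#' seen in TaCESA7, then the older literature consensus; for each pattern
#' the most N-terminal hit wins. Deletion size is reported relative to the
#' 46-AA consensus.
#'
#' @param protein A [protein_record].
#' @return List with `variant` (`"full_46"`, `"deleted_38"`, `"literature"`
#'   or `"none"`), `deletion_size` (residues, `NA` when no hit), and `hit`
#'   (one-row hit data frame, or `NULL`).
#' @export
detect_znf <- function(protein) {
  for (variant in names(ZNF_PATTERNS)) {
    pat <- compile_pattern(ZNF_PATTERNS[[variant]], name = paste0("znf_", variant))
    hits <- scan_motif(protein, pat)
    if (nrow(hits)) {
      return(list(
        variant = variant,
        deletion_size = 46L - pat$length,
        hit = hits[1L, , drop = FALSE]
      ))
    }
  }
  list(variant = "none", deletion_size = NA_integer_, hit = NULL)
}

#' Locate the D, DXD, D, QXXRW catalytic signature
#'
#' The search is anchored on the first `QXXRW` occurrence. Upstream of it
#' the nearest `DXD` is taken (its first aspartate is D2), then D3 is the
#' aspartate nearest to QXXRW strictly between the DXD and the anchor, and
#' D1 the aspartate nearest to (and upstream of) the DXD. All four elements
#' must be found, in order D1 < D2 < D3 < QXXRW, otherwise the signature is
#' reported absent.
#'
#' @param protein A [protein_record].
#' @return List with `present` and, when present, 0-based positions `d1`,
#'   `d2`, `d3` and `qxxrw` (start of the 5-mer).
#' @export
detect_catalytic <- function(protein) {
  seq <- protein$sequence
  absent <- list(present = FALSE, d1 = NA_integer_, d2 = NA_integer_,
                 d3 = NA_integer_, qxxrw = NA_integer_)
  q_hits <- scan_motif(protein, compile_pattern("QXXRW", "qxxrw"))
  if (!nrow(q_hits)) return(absent)
  q <- q_hits$start[1L]
  chars <- strsplit(seq, "")[[1]]
  d_pos <- which(chars == "D") - 1L                   # 0-based
  dxd_hits <- scan_motif(protein, compile_pattern("DXD", "dxd"))
  dxd_hits <- dxd_hits[dxd_hits$end <= q, , drop = FALSE]
  if (!nrow(dxd_hits)) return(absent)
  # nearest DXD to the anchor that still leaves room for D1 and D3
  for (i in rev(seq_len(nrow(dxd_hits)))) {
    d2 <- dxd_hits$start[i]
    d3_cand <- d_pos[d_pos > d2 + 2L & d_pos < q]
    d1_cand <- d_pos[d_pos < d2]
    if (length(d3_cand) && length(d1_cand)) {
      return(list(present = TRUE,
                  d1 = max(d1_cand), d2 = d2, d3 = max(d3_cand), qxxrw = q))
    }
  }
  absent
}

# Kyte-Doolittle hydropathy index.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Call transmembrane segments by sliding-window hydropathy
#'
#' Kyte-Doolittle hydropathy is averaged over a centered sliding window;
#' maximal runs of positions whose window mean reaches the threshold become
#' candidate segments. Runs separated by a gap shorter than half the window
#' are merged, and every reported interval is extended to at least the
#' window length (centered, clipped to the sequence).
#'
#' @param protein A [protein_record].
#' @param window Odd window width (residues), default 19.
#' @param threshold Window-mean hydropathy threshold, default 1.6.
#' @return Integer matrix of disjoint, sorted intervals (`start`, `end`,
#'   0-based half-open); zero rows when no segment is called.
#' @export
tmd_scan <- function(protein, window = 19L, threshold = 1.6) {
  if (window %% 2L == 0L || window < 5L) {
    stop_cesafam("bad_window", "window must be an odd integer >= 5")
  }
  seq <- protein$sequence
  L <- nchar(seq)
  if (window > L) {
    stop_cesafam("bad_window", "window exceeds sequence length")
  }
  h <- KYTE_DOOLITTLE[strsplit(seq, "")[[1]]]
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  above <- !is.na(means) & means >= threshold
  if (!any(above)) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])     # 1-based inclusive positions
  # merge runs separated by less than window/2
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      if (runs[i, 1] - merged[nrow(merged), 2] - 1L < window / 2) {
        merged[nrow(merged), 2] <- runs[i, 2]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
  }
  # extend each interval to at least the window length, clipped to sequence
  out <- t(apply(merged, 1L, function(iv) {
    s <- iv[1] - 1L    # to 0-based
    e <- iv[2]
    short <- window - (e - s)
    if (short > 0) {
      s <- max(0L, s - ceiling(short / 2))
      e <- min(L, s + window)
      s <- max(0L, e - window)
    }
    c(s, e)
  }))
  colnames(out) <- c("start", "end")
  storage.mode(out) <- "integer"
  out
}

#' Annotate a protein with CESA domains
#'
#' Bundles [detect_znf()], [detect_catalytic()], [tmd_scan()] and scans of
#' any additional class-diagnostic motifs into one annotation record.
#'
#' @param protein A [protein_record].
#' @param extra_patterns Optional list of compiled [motif_pattern]s to scan
#'   in addition (e.g. an ortholog-specific motif table).
#' @param tmd_window,tmd_threshold Passed to [tmd_scan()].
#' @return An object of class `domain_annotation`: list with `protein_id`,
#'   `znf`, `catalytic`, `tmds` and `class_motif_hits`.
#' @export
annotate_domains <- function(protein, extra_patterns = list(),
                             tmd_window = 19L, tmd_threshold = 1.6) {
  hits <- lapply(extra_patterns, function(p) scan_motif(protein, p))
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(pattern_name = character(0), start = integer(0),
               end = integer(0), matched = character(0))
  structure(
    list(
      protein_id = protein$id,
      znf = detect_znf(protein),
      catalytic = detect_catalytic(protein),
      tmds = tmd_scan(protein, tmd_window, tmd_threshold),
      class_motif_hits = hits
    ),
    class = "domain_annotation"
  )
}

#' Read a motif table from a config file
#'
#' One pattern per line: `name<TAB>spec<TAB>class_tag`; `#` comments and
#' blank lines ignored.
#'
#' @param path Path to the table.
#' @return Named list of compiled [motif_pattern]s; the class tag is
#'   attached as attribute `class_tag`.
#' @export
read_motif_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t")[[1]]
    if (length(parts) < 2L) {
      stop_cesafam("bad_motif_table", sprintf("malformed motif line: '%s'", ln))
    }
    pat <- compile_pattern(parts[2], name = parts[1])
    attr(pat, "class_tag") <- if (length(parts) >= 3L) parts[3] else NA_character_
    out[[parts[1]]] <- pat
  }
  out
}
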