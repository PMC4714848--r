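# Primary- vs secondary-cell-wall classification of CESA-like proteins.
#
# Two independent evidence channels, both rooted in motifs conserved across
# land-plant CESAs:
#   1. the dipeptide inside the first C-X2-C pair of the zinc finger
#      (CQIC in PCW CESAs; CEIC, CAAC, CRAC in the SCW CESA4/7/8 orthologs);
#   2. the second-transmembrane-domain motif around the conserved
#      S-X-X-C-E-X-W-F core (SVICEXWFA in PCW CESAs; SVLCE.WFA, SVICE.WFG
#      and SIVCE.WFA in the SCW CESA4/7/8 orthologs).
# Agreement of the two channels gives a high-confidence call; a single
# informative channel a low-confidence one; disagreement yields "unknown".

ZNF_DIPEPTIDE_TABLE <- list(
  QI = list(call = "PCW", hint = "PCW-type"),
  EI = list(call = "SCW", hint = "CesA4-like"),
  AA = list(call = "SCW", hint = "CesA7-like"),
  RA = list(call = "SCW", hint = "CesA8-like")
)

# TM2 variants keyed by (positions 2,3 of the core, residue after the F).
# Position 6 of SXXCEXWF (the E+1 wildcard) is never evidence.
TM2_VARIANT_TABLE <- list(
  "VI.A" = list(label = "SVICExWFA", call = "PCW", hint = "PCW-type"),
  "VL.A" = list(label = "SVLCExWFA", call = "SCW", hint = "CesA4-like"),
  "VI.G" = list(label = "SVICExWFG", call = "SCW", hint = "CesA7-like"),
  "IV.A" = list(label = "SIVCExWFA", call = "SCW", hint = "CesA8-like")
)

#' Zinc-finger dipeptide rule
#'
#' Extracts the two residues inside the first `C-X2-C` pair of a matched
#' zinc finger and maps them to a wall-class call: `QI` is the PCW
#' diagnostic (the CQIC motif); `EI`, `AA` and `RA` mark the SCW CESA4, 7
#' and 8 ortholog groups; anything else is uninformative.
#'
#' @param annotation A `domain_annotation` (from [annotate_domains()]) whose
#'   zinc finger was found.
#' @param protein The corresponding [protein_record].
#' @return List with `dipeptide`, `call` (`"PCW"`, `"SCW"` or `"unknown"`)
#'   and `ortholog_hint`.
#' @export
znf_dipeptide_rule <- function(annotation, protein) {
  znf <- annotation$znf
  if (is.null(znf) || znf$variant == "none") {
    stop_cesafam("znf_absent",
                 sprintf("protein '%s': no zinc finger located", protein$id))
  }
  # every ZnF preset begins C-X2-C, so the diagnostic pair sits at offsets 1-2
  dipeptide <- substr(znf$hit$matched, 2L, 3L)
  entry <- ZNF_DIPEPTIDE_TABLE[[dipeptide]]
  if (is.null(entry)) {
    list(dipeptide = dipeptide, call = "unknown", ortholog_hint = "none")
  } else {
    list(dipeptide = dipeptide, call = entry$call, ortholog_hint = entry$hint)
  }
}

#' Second-transmembrane-domain motif rule
#'
#' Scans for the conserved `SXXCEXWF` core; at the first hit, positions 2-3
#' and the residue following the F decide the variant: `SVICE.WFA` is PCW;
#' `SVLCE.WFA`, `SVICE.WFG` and `SIVCE.WFA` are the SCW CESA4, 7 and 8
#' variants. A core hit outside the table is uninformative (`"unknown"`);
#' no core at all reports variant `"none"`.
#'
#' @param protein A [protein_record].
#' @return List with `variant` (label), `call` and `ortholog_hint`.
#' @export
tm2_motif_rule <- function(protein) {
  core <- compile_pattern("SXXCEXWF", "tm2_core")
  hits <- scan_motif(protein, core)
  if (!nrow(hits)) {
    return(list(variant = "none", call = "none", ortholog_hint = "none"))
  }
  h <- hits[1L, ]
  m <- h$matched
  after_f <- substr(protein$sequence, h$end + 1L, h$end + 1L)
  key <- paste0(substr(m, 2L, 3L), ".", after_f)
  entry <- TM2_VARIANT_TABLE[[key]]
  if (is.null(entry)) {
    list(variant = paste0(m, after_f), call = "unknown", ortholog_hint = "none")
  } else {
    list(variant = entry$label, call = entry$call, ortholog_hint = entry$hint)
  }
}

#' Classify a CESA-like protein as PCW or SCW
#'
#' Combines the zinc-finger dipeptide rule and the TM2 motif rule. Both
#' channels agreeing gives the shared call with high confidence; one
#' informative channel gives its call with low confidence; disagreement or
#' no informative channel yields `"unknown"`.
#'
#' @param protein A [protein_record].
#' @param annotation Optional pre-computed `domain_annotation`; computed
#'   on the fly when omitted.
#' @return An object of class `wall_call`: list with `protein_id`, `call`,
#'   `confidence` (`"high"`, `"low"`, `"none"`), `znf_dipeptide`,
#'   `tm2_variant`, `ortholog_hint` and `evidence` (the per-channel calls).
#' @export
classify_wall <- function(protein, annotation = NULL) {
  if (is.null(annotation)) annotation <- annotate_domains(protein)
  znf_ev <- if (!is.null(annotation$znf) && annotation$znf$variant != "none") {
    znf_dipeptide_rule(annotation, protein)
  } else {
    list(dipeptide = NA_character_, call = "none", ortholog_hint = "none")
  }
  tm2_ev <- tm2_motif_rule(protein)

  informative <- function(ev) ev$call %in% c("PCW", "SCW")
  zi <- informative(znf_ev)
  ti <- informative(tm2_ev)
  if (zi && ti) {
    if (znf_ev$call == tm2_ev$call) {
      call <- znf_ev$call
      confidence <- "high"
      hint <- if (znf_ev$ortholog_hint == tm2_ev$ortholog_hint)
        znf_ev$ortholog_hint else "none"
    } else {
      call <- "unknown"
      confidence <- "none"
      hint <- "none"
    }
  } else if (zi || ti) {
    ev <- if (zi) znf_ev else tm2_ev
    call <- ev$call
    confidence <- "low"
    hint <- ev$ortholog_hint
  } else {
    call <- "unknown"
    confidence <- "none"
    hint <- "none"
  }
  structure(
    list(
      protein_id = protein$id,
      call = call,
      confidence = confidence,
      znf_dipeptide = znf_ev$dipeptide,
      tm2_variant = tm2_ev$variant,
      ortholog_hint = hint,
      evidence = list(znf = znf_ev, tm2 = tm2_ev)
    ),
    class = "wall_call"
  )
}

#' @export
print.wall_call <- function(x, ...) {
  cat(sprintf("<wall_call> %s: %s (%s confidence; ZnF dipeptide %s, TM2 %s, hint %s)\n",
              x$protein_id, x$call, x$confidence,
              ifelse(is.na(x$znf_dipeptide), "-", x$znf_dipeptide),
              x$tm2_variant, x$ortholog_hint))
  invisible(x)
}

#' Tabulate wall calls for a set of proteins
#'
#' @param proteins List of [protein_record]s.
#' @return Data frame with one row per protein: `protein_id`, `call`,
#'   `confidence`, `znf_dipeptide`, `tm2_variant`, `ortholog_hint`.
#' @export
classify_wall_table <- function(proteins) {
  rows <- lapply(proteins, function(p) {
    wc <- classify_wall(p)
    data.frame(
      protein_id = wc$protein_id, call = wc$call, confidence = wc$confidence,
      znf_dipeptide = ifelse(is.na(wc$znf_dipeptide), ".", wc$znf_dipeptide),
      tm2_variant = wc$tm2_variant, ortholog_hint = wc$ortholog_hint,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
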