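---
title: "Methods: motif scanning, intron phases, phylogenetics and expression clustering for CesA families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif scanning, intron phases, phylogenetics and expression clustering for CesA families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cesafam)
```

This vignette is the package's account of its methods: the models and
procedures, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## The degenerate-motif grammar

CESA literature writes motifs as strings of fixed residues and wildcard
runs — `CX2-CX14-ACX2-CX4-CX2-CX7-GX3-CX2-C` is the 46-residue zinc-finger
consensus of the wheat CESAs, `QXXRW` the glycosyltransferase anchor. The
compiler accepts exactly that notation: a residue letter matches itself,
`X` (optionally with an integer repeat) matches any of the 20 canonical
amino acids, and `-`, parentheses and whitespace are ignored so published
strings parse verbatim. A wildcard never matches a gap: scanning operates
on unaligned protein sequences. Scanning reports **all** occurrences,
including overlapping ones, left to right; consumers that need one hit take
the first (most N-terminal). This is lossless and makes downstream rules
deterministic.

Two grammar corner cases worth recording: a repeat count of zero is an
error rather than an empty run, and the older literature zinc-finger
consensus `(CX2-CX12-FXACX2-CX2PXCX2-CXEX5-GX3-CX2C)` is tokenized
literally as written (its length comes out to 46), since its printed form
is ambiguous about grouping; it is only a third-choice fallback after the
wheat 46-residue consensus and the 38-residue deletion variant.

## Domain detection

**Zinc finger.** `detect_znf` tries the 46-residue consensus, then the
8-residue-deletion variant (seen in CesA7-type proteins), then the
literature preset, reporting the most N-terminal hit of the first pattern
that matches and a deletion size relative to 46. Trying the full pattern
first means a protein containing both variants is labeled by the intact
consensus, which is the informative one.

**Catalytic signature.** The search is anchored on the first `QXXRW`
occurrence because it is the most constrained element; the aspartates are
then resolved by nearest-neighbor selection — the closest `DXD` upstream of
the anchor that still leaves an isolated aspartate on either side, D3 the
aspartate nearest the anchor, D1 the aspartate nearest the `DXD` from
upstream. The field's alignments give no canonical spacings, so a
deterministic, order-respecting rule was chosen over any distance prior.
The ordering D1 < D2 < D3 < QXXRW is enforced; anything unresolvable is
reported absent rather than guessed.

**Transmembrane segments.** A Kyte–Doolittle sliding-window caller with
window 19 and threshold 1.6 — the standard hydropathy convention for
membrane-spanning helices; no method is prescribed by the source analyses,
which relied on pre-annotated domains. Runs of above-threshold window means
are merged when separated by less than half a window (avoiding split calls
across a single helix) and each call is extended to at least one window
length, so a reported segment is never shorter than the physical minimum
the scale was calibrated for. Intervals are disjoint and sorted by
construction.

## Wall-class calling

Two independent evidence channels are read:

1. the dipeptide inside the first `C-X2-C` of the matched zinc finger
   (`QI` PCW; `EI`/`AA`/`RA` the CesA4/7/8 SCW ortholog groups). The
   consensus itself begins `C-X2-C`, which fixes the anchor without any
   further search;
2. the TM2 motif: first hit of the conserved core `SXXCEXWF`, with
   positions 2–3 and the residue after the F deciding the variant
   (`VI…A` PCW, `VL…A` CesA4, `VI…G` CesA7, `IV…A` CesA8). The wildcard
   position after the E is deliberately never used as evidence — it is
   variable across species.

Agreement gives the call at high confidence; a single informative channel
gives low confidence; disagreement yields `unknown` with both evidences
reported, rather than a priority rule — the motifs are described as
concordant in real families, so a conflict is out-of-distribution and
should surface, not be silently resolved. The invariant `unknown ⇔ no
confidence` is enforced structurally. Ortholog-group motif tables beyond
these two channels can be supplied as a config file (`read_motif_table`)
and are reported as additional named hits; none ship with the package
because their residue strings are published only as figures.

## Intron phases

The phase of intron *i* is the cumulative coding-exon length up to exon
*i*, modulo 3 — 0 between codons, 1 after the first base, 2 after the
second. Phases are computed from coding exons only, in translation order,
which makes them strand-invariant by construction. Percentage renderings
round half-up to integers (so 6/9 = 66.7% prints as 67); full-precision
values are kept alongside. The wheat family's four published phase
assignments (the common PCW pattern with 13 introns and the CesA4/7/8
patterns with 7, 12 and 9) are shipped as `cesa_phase_sets()` and
reproduce the family statistics: phase 0 dominant in every gene
(57.1–66.7%), then phase 1 (22.2–28.6%), then phase 2 (11.1–16.7%).
ORF length in amino acids is computed as (coding length − 3)/3, i.e. the
stop codon is removed before translation-length arithmetic, matching the
published per-gene ORF lengths.

The published gene-length table and the prose describing the family's
length range disagree for two genes; the shipped structure table
(`cesa_structure_table()`) follows the table, and nothing is asserted on
the prose range.

## Distance phylogenetics

The tree stage mirrors the standard MEGA-style protocol for protein
families: **complete deletion** (every column containing a gap or an
ambiguity letter in any row is removed — ambiguity characters count as
missing data), **Poisson correction** `d = −ln(1 − p)` of pairwise
p-distances (equal rates across sites; undefined at p = 1, which is a
named error rather than an infinity), and **Saitou–Nei neighbor joining**.
Ties in the Q criterion are broken by the smallest (row, column) index
pair, making the topology deterministic on degenerate inputs. Negative
branch-length estimates — a known NJ artifact on non-additive matrices —
are clamped to zero with the summed deficit recorded on the tree, the
convention familiar from mainstream phylogenetics GUIs. On additive
matrices the algorithm is exact: the test suite verifies topology and
path-length recovery to 1e−9 on random 5–8-taxon trees, cross-checked
against an independent NJ implementation.

Bootstrap supports use column resampling with replacement, re-running the
whole complete-deletion → Poisson → NJ pipeline per replicate, and
**support mapping**: each internal edge of the full-data tree is scored by
the percentage of replicate trees containing the same bipartition
(bipartitions are canonicalized on the side not containing a fixed
reference leaf, so the scoring is correct for unrooted trees and invariant
under leaf relabeling). Majority-rule consensus trees are not built; the
full-data topology is the object of interest and supports annotate it.
Replicates whose resampled columns leave a saturated pair (p = 1) or no
columns at all are skipped and counted; more than half skipped aborts the
run. The default is 1000 replicates; the test suite uses 100, which is
ample for the showcase family's deep clades.

## Expression clustering

The heat-map pipeline is counts → CPM → `log2(CPM + 0.5)` → per-gene
z-scores → Ward clustering on Pearson correlation distances, for genes and
samples independently.

- **Pseudocount 0.5** inside the log: no value is prescribed by the
  protocol being mirrored; 0.5 is the common small-count convention and
  keeps zeros finite.
- **Population (divide-by-n) standard deviation** in the z-scores: the
  heat-map scaling convention; either choice is defensible and this one is
  documented and tested.
- **`ward.D2`**: the textbook Ward criterion (squared-distance update);
  "Ward's linkage" alone is ambiguous in R's history, and `ward.D2` is the
  variant that actually minimizes within-cluster variance increase on the
  supplied distances.
- **`d = 1 − r`**, not `1 − |r|`: anti-correlated profiles are maximally
  distant, the standard reading of "correlation distance" for expression
  profiles.
- The z-scoring is row-wise (per gene), the usual reading of a
  "deviation-of-log2-CPM" heat map; a global scaling would mix
  between-gene magnitude into the picture the clustering is meant to
  abstract away. For users who want that alternative it is available as
  `heatmap_matrix(counts, scaling = "global")`, which standardizes the
  whole log2-CPM matrix by its grand mean and population sd.

Zero-variance genes cannot be z-scored or correlated; they are flagged,
warned about and dropped from clustering rather than silently imputed.
Merge heights under Ward are monotone, and the exported heat-map matrix is
ordered by the two dendrograms' leaf orders.

## The synthetic-data generator

The generator defines the study conditions and records ground truth for
every object; the tests and the acceptance script measure the pipeline
against that truth.

**Proteins** (`make_cesa_protein`) realize the canonical CESA layout:
N-terminal spacer, zinc finger (46- or 38-residue variant, diagnostic
dipeptide set by class), two N-terminal transmembrane 21-mers with the TM2
class motif embedded in the second, a catalytic region with
D…DXD…D…QXXRW at randomized 12–25-residue spacings, six C-terminal
transmembrane 21-mers separated by 25-residue linkers, and padding
distributed into the catalytic flanks so total length lands in the
class-typical range (1075–1091 residues for PCW, 991–1055 for SCW, the
published size ranges). Three alphabet rules make the ground truth exact
rather than probable:

- cysteine and tryptophan occur **only** at motif-fixed positions, so the
  zinc finger, the `SXXCEXWF` core and `QXXRW` cannot arise spuriously;
- linkers use a strictly hydrophilic alphabet (every Kyte–Doolittle value
  negative), so no spurious window can cross the 1.6 threshold and the
  transmembrane count is exactly eight by construction — detectable
  without tuning, since a 19-window inside a hydrophobic 21-mer averages
  well above threshold even with the TM2 motif's polar residues embedded;
- aspartate is excluded from fillers inside the catalytic region, so the
  nearest-neighbor D/DXD/D search resolves to the planted residues.

**Families** (`evolve_family`) evolve a root protein along a tree under a
Poisson replacement process: each site receives a Poisson(branch-length)
number of events, each replacing the residue uniformly among the other 19
— the same equal-rates assumption the Poisson distance correction inverts.
No indels are simulated, so the leaf set is its own alignment and complete
deletion is a no-op on clean families. The exact parent–descendant
divergence for this process is `p = (19/20)(1 − e^(−20t/19))` at branch
length *t*, which the suite verifies within binomial error at 1000+ sites.
Diagnostic-motif positions can be protected from substitution; with
protection on, every leaf classifies identically to the root. The
documented showcase (`showcase_family`, seed 42) has three ortholog clades
of three species each (clade stems 0.4, tips 0.05 substitutions/site),
mirroring the orthologs-cluster-before-paralogs structure of real CESA
trees; its clades are recovered with 100/100 bootstrap support.

**Gene models** (`make_gene_model`) invert the phase arithmetic: exon
lengths (each ≥ 30 nt, totals a multiple of three) are drawn so the
cumulative sums modulo 3 realize any requested phase vector; the request
itself is the ground truth and round-trips exactly through
`intron_phases`.

**Counts** (`make_counts`) emulate the organ-by-stage RNA-seq design used
for the wheat family: five organs at three stages each (15 samples), a
7-gene SCW group and a 14-gene PCW group (the heat-map composition), with
negative-binomial counts at dispersion 0.1, the SCW group 10-fold elevated
in the two mature-stem samples and the PCW group 5-fold elevated
elsewhere. Those folds give a clean two-block correlation structure, so
the top-level Ward split recovers the labels; dispersion 0 with fold 1 is
the documented null in which the split is uninformative.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: insertions/deletions and alignment
uncertainty; rate heterogeneity across sites and lineages; hypervariable
regions and partial (N-terminally truncated) proteins; homoeolog-level
divergence (real wheat homoeologs are 95–99% identical, far closer than
the showcase clades); library-composition effects that CPM cannot remove;
and biological intermediate expression patterns between the two groups.
Real-data runs should expect `unknown` calls, missing zinc fingers and
lower bootstrap supports, which is why every detector reports absence
explicitly instead of failing.

## Problem sizes and determinism

All generation and resampling is seeded, and equal seeds give
byte-identical FASTA/GFF3/TSV outputs. The suite's chosen sizes — 100
labeled proteins for classifier accuracy, 50 random additive matrices of
5–8 taxa for NJ exactness, 100 bootstrap replicates on the 9-leaf
showcase, 1000 random genes for the phase oracle, a 21 × 15 count matrix —
are the package's own desk-scale study conditions: large enough that the
all-or-nothing claims (exact recovery, zero classification errors) are
meaningful, small enough to re-run routinely. The analysis drivers under
`analysis/` run the same stages at the same sizes, with the bootstrap at
its 1000-replicate default.

## Known limitations

- The catalytic-core rule is a deterministic convention, not a learned
  model; proteins with unusual aspartate spacing may be reported absent.
- The hydropathy caller has no length upper bound and will merge helices
  separated by very short loops.
- The two-domain decomposition of the CESA zinc-finger region is not
  modeled; the consensus is treated as one unit, as family-level analyses
  treat it.
- `tm2_motif_rule` trusts the first `SXXCEXWF` hit; a pathological protein
  with an earlier spurious core would be misread (impossible for generated
  proteins by the alphabet rules, rare in real CESAs).
- NJ is exact only on additive inputs; on real distance matrices the
  clamped-deficit attribute should be inspected.
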