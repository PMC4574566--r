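---
title: "In silico hybridization: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico hybridization: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybscreen)
```

## The problem and the model

Histone variant genes are hard to find by nucleotide homology: selection
acts on the protein, so duplicated histone genes drift apart in synonymous
codon positions while still encoding near-identical proteins, and many such
loci sit unannotated or mislabelled as pseudogenes. `hybscreen` searches at
the level where the conservation actually lives. A query protein is cut
into overlapping `k`-residue windows (stride 1), and each window is treated
as the *set* of all DNA sequences that could encode it under the standard
genetic code. A genomic segment "hybridizes" to a window when it is exactly
one of those realizations — equivalently, when its translation in its own
local reading frame equals the window peptide. Synonymous divergence is
therefore invisible to the screen by construction, which is the method's
defining property (and a tested invariant: recoding every codon of an
implant synonymously changes neither the reported locus span nor the
predicted protein).

Matching is exact at codon level. Amino-acid substitutions are tolerated
*between* windows, not within them: a variant is discoverable as long as it
retains at least one run of `k + 1` consecutive query-identical residues,
which yields two overlapping window hits within the merge gap and hence a
locus. With `k = 8` the sensitivity cutoff is a 9-residue conserved run —
far below the conservation of any functional histone-fold protein, but a
real limit for highly diverged pseudogene fragments.

## Pipeline stages and their parameters

| parameter | default | units | role |
|---|---|---|---|
| `k` | 8 | aa | window length; sets specificity (24-nt match) and the `k+1`-run sensitivity rule |
| `max_gap` | 90 | nt | end-to-start gap joining consecutive hits into one locus (inclusive) |
| `min_distinct` | 2 | windows | distinct window peptides required per locus; 1 hit is never a locus |
| `min_peptide_len` | 10 | aa | minimum predicted peptide length |
| `core_range` | 63–135 | mature residues | query core domain that must be covered in one uninterrupted frame |
| `promoter_halfwidth` | 2000 | nt | promoter = TSS ± halfwidth (width 2 × halfwidth, half-open) |
| `utr_span` | 3000 | nt | putative 3′-UTR downstream of a CDS end |
| `search_span` (3′ end) | 800 | nt | downstream window searched for stem-loop / poly-A signal |

The stage counts (windows, enumerable sequences, hits, loci, after the
length filter, after the core filter) are always recorded in the
`hyb_screen` summary; they are the screen's reproducibility surface.

Counting note: the total number of realizations is computed in closed form
as a sum over windows of per-residue degeneracy products. Two windows share
a realization exactly when their peptides are identical, so the
deduplicated total (`distinct = TRUE`) is the same sum over *unique* window
peptides. The 136-aa H3.2 query has no repeated 8-mer, so both totals equal
4,162,752.

```{r counts}
w <- make_windows(h3_query())
nrow(w)
count_reverse_translations(w)
count_reverse_translations(w, distinct = TRUE)
```

## Numbering conventions

Genomic intervals are 0-based half-open everywhere internally, BED and GFF3
exports follow their own conventions, and the human-facing TSV reports are
1-based inclusive. Protein positions are reported in *mature* numbering
(position 1 = residue after the cleaved initiator methionine), the histone
convention in which K4/K27/S28/A31 and the 87–90 motif are named; the
built-in H3.2 query carries `numbering_offset = 1` for this reason. The
core-domain default, mature 63–135, spans the histone-fold α1–L1–α2–L2–α3
region whose integrity the screen requires; it is a package default chosen
on structural grounds and is configurable per query.

## ORF reconstruction and the core-domain filter

Hits in a locus vote on a dominant reading frame (majority, ties to the
anchor), and the ORF is the maximal stop-to-stop stretch in that frame that
best covers the member hits — no ATG is required, because the screen
targets coding exons rather than full gene models (ATG anchoring is
available behind `require_atg`).

The core-domain filter is deliberately anchored at the *most N-terminal*
matched window rather than the majority frame. A frameshift early in a
gene leaves the downstream DNA intact, so downstream windows still match —
in a frame shifted by one. Majority voting would then adopt the downstream
frame and see an intact core, even though no single reading frame produces
a full-length histone from this locus; that is precisely the lesion that
defines a frameshift pseudogene. Anchoring at the N-terminal hit makes the
check read like translation does: the core is accepted only if every
core-overlapping hit shares the anchor's alignment offset and the
anchor-frame translation runs from the anchor through the projected core
end without a stop codon or a contig edge. An early frameshift breaks the
offset agreement, a premature stop breaks the stop-free requirement, and a
frameshift strictly downstream of the core end leaves the check intact (the
locus can pass) — all three behaviours are exercised in the tests.

Loci are merged by single-linkage chaining with an inclusive `max_gap`
measured end-to-start, so intron-containing genes surface as one locus per
exon; clusters are never bridged across larger gaps. `min_distinct` counts
distinct window *peptides*, the permissive reading of "two or more
different sequences", and is configurable.

## Characterization choices

Levenshtein distance is the package's own dynamic program (row-vectorized),
tested against an independent top-down recursion oracle on all short pairs
and against `utils::adist` on longer random pairs. Percent identity uses
the longer sequence as denominator. Substitution notation falls back to the
compact `#d` form when sequences differ in length or in more than 10
positions, mirroring the convention used for distant variants.

Grouping clusters candidates together with the H3.1/H3.2/H3.3 references
by average linkage on the pairwise edit-distance matrix. Average linkage is
chosen so dendrogram heights stay interpretable as mean inter-cluster edit
distances; single and complete linkage are available by argument. The tree
is cut into four clusters (the cut deepens automatically if the H3.1 and
H3.3 references coincide); the two clusters not containing references are
ranked by mean distance to H3.3, nearer = distant-A, farther = distant-B,
so the boundary derives from the tree topology rather than hard-coded
substitution counts.

The 3′-end classifier searches a 800-nt downstream window — generous
relative to the short 3′-UTRs typical of histone genes — for a histone
stem-loop first (a 16-mer with a perfectly self-complementary 6-bp stem and
a 4-nt loop matching `^TT[TC]`, pattern configurable), then for an
AATAAA/ATTAAA polyadenylation signal; stem-loop takes precedence because a
replication-dependent histone 3′ end is the stronger structural claim. No
published definition of the stem-loop call was available to copy, so the
structural stem check plus loop consensus is this package's choice; the
canonical 16-mer `GGCTCTTTTCAGAGCC` is used by the simulator.

## What the simulator emulates — and what it does not

`simulate_genome()` produces i.i.d. background chromosomes (GC 0.42,
roughly mammalian) with implanted elements of five kinds: exact query CDS
copies, synonymously recoded copies, amino-acid-substituted variants
(substitutions spaced ≥ `k + 2` apart so each variant stays detectable),
frameshift pseudogenes, and truncated fragments. Every implant is a
stop-bracketed cassette (`TAA` + CDS + `TAA`), so stop-to-stop ORF
reconstruction recovers exactly the implanted protein and truth coordinates
are well-defined. Downstream regions are screened free of chance poly-A
hexamers and stem-loops before the requested motif is written, and the
finished genome is screened for chance loci outside the truth intervals
(any are resampled) — so sensitivity and specificity statements in the
tests are exact by construction.

The default `demo_implants()` panel (20 elements across both strands and
all three 3′-end classes) represents the study conditions: a histone-like
gene family of near-identical coding copies, recoded paralogs, diverged
variants, and broken pseudogenes embedded in neutral sequence.

What the simulator does *not* model: repeat families and segmental
duplications (which inflate multi-hit counts in real genomes), introns
inside implants, indel/substitution phylogenies, base-composition
heterogeneity, and aligner mismatch tolerance. Passing the synthetic tests
therefore demonstrates correctness of the screen's logic, not concordance
with published full-genome counts — reproducing those requires the original
reference genome and annotation version, and depends on the mismatch policy
of the aligner used there, which exact codon-level matching intentionally
does not emulate.

## Problem sizes used in the tests

The test suite validates the scan against the enumerate-and-match oracle on
50 fuzzed genomes of 5–40 kb with queries capped at 2 × 10⁴ realizations
(sizes chosen to keep the full enumeration cheap while covering empty,
implanted, and multi-hit cases), recovers a seeded 20-implant genome
against its truth table, and checks synonymous invariance across 1,000
random recodings of the full query CDS in a small genome. Degenerate
inputs — empty hit sets, contig-edge loci, N runs, zero peaks, zero
mapped reads — have dedicated tests.

## Known limitations

* Exact matching only; no mismatch or gapped tolerance within a 24-nt
  window. Variants without any 9-residue conserved run are invisible.
* Multi-exon genes appear as one locus per exon; no spliced gene model is
  assembled.
* The distant-A/distant-B boundary depends on the candidate set through the
  clustering; with very sparse candidate sets a lone distant cluster is
  labelled distant-A.
* Stem-loop detection is consensus-based; RNA folding is not computed.
* `refFlat` input is taken in its native UCSC 0-based half-open convention;
  GTF is converted from 1-based inclusive on import.
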