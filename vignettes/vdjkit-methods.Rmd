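---
title: "Models and methods behind vdjkit"
author: "vdjkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vdjkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdjkit)
```

# The problem

T- and B-cell antigen receptors are assembled by somatic recombination of
germline V, D and J gene segments. Annotating these segments in a new genome
assembly is laborious because the segments are short, occur in large
near-identical families, and are defined less by sequence conservation than
by a *grammar* of features: conserved amino-acid anchors inside the V exon,
conserved nucleotide motifs in J segments, splice signals, and the
recombination signal sequences (RSSs) that the RAG recombinase binds. An RSS
is a conserved heptamer beginning `CAC`, a 12- or 23-nucleotide spacer
(either may vary by one base), and an A-rich nonamer; segments with unlike
spacers recombine (the 12/23 rule).

`vdjkit` implements this grammar as a scanner over genomic DNA, an
IMGT-style functionality classifier (F / ORF / P), a family clustering and
naming layer, the shorter-sequence-normalized comparison formulas used to
reconcile annotations across studies, and post-clonotyping repertoire
statistics for AIRR-style clonotype tables. A seeded simulator produces
ground-truthed synthetic loci and repertoires so that every stage is testable
without external data.

# The scanner model

## What counts as a V candidate

On each strand, a V candidate is an interval that simultaneously satisfies:

* an opening: either an in-frame `ATG` (single-exon leader, as in chicken
  Vα1 genes where the signal peptide is encoded with the V gene) or an `AG`
  splice acceptor immediately 5' of the exon (spliced leader, any of the
  three frames);
* an open reading frame from that opening to the RSS with no stop codon;
* the three conserved V-domain anchors in the translated exon: the 1st-CYS
  (first cysteine inside a configurable window, default residues 15–40), the
  CONSERVED-TRP (10–20 residues downstream of the 1st-CYS) and the rightmost
  2nd-CYS motif (`YYC/YFC/YLC/YHC/YIC/TFC`, starting at residues 80–115);
* a 3' 23-class RSS whose heptamer literally begins `CAC`; the candidate
  ends at the base before the `CAC`;
* a total length inside a configurable window (default 240–360 nt,
  consistent with restricting downstream comparisons to full-length V genes
  longer than 222 bp).

The anchor windows bracket typical IMGT V-domain geometry; they are
deliberately configuration-exposed (`vdjConfig()`, or a `key = value` file
via `readConfig()`) because different loci and species shift them by a few
residues.

## What counts as a J candidate

A J candidate runs from the base after its 5' 12-class RSS to the base
before a `GTRDGD` splice donor, requires the J core `TTYGGNNNNGG` (whose
first two codons necessarily translate `FG`, the conserved J motif), no stop
codon in the core-anchored reading frame, and a length between 40 and 75 nt.
The `TNNBNRT` motif is treated as a confirmatory criterion that must occur
between the core and the donor; its exact positional role is not fixed by
any published rule we know of, so `relaxJSecondary = TRUE` demotes it to a
note. All IUPAC degeneracy is honoured literally (`Y = {C,T}` and so on),
with one deliberate exception: an `N` in the *subject* never matches
anything, so motifs are never called inside assembly gaps.

## The operational RSS model

The scanner anchors an RSS on the literal `CAC` adjacent to the gene
boundary and then *pins the spacer length* by locating the nonamer consensus
(`ACAAAAACC`, up to 2 mismatches, both configurable) at spacer offsets
`{11,12,13}` or `{22,23,24}`. The spacer here is measured from the end of the
`CAC` anchor to the nonamer start. This is a motif criterion, not a
probabilistic RSS model: full heptamer/nonamer information-content scoring
(RIC-style) is the province of dedicated external predictors and is exposed
as `rssScoreHook` instead of being reimplemented. Without the nonamer the
spacer length would be unobservable, and the tolerance rule ("12 ± 1,
23 ± 1") undecidable. Consequences of this choice:

* a spacer two or more bases off the canonical length is rejected even if a
  perfect nonamer follows it;
* an RSS whose nonamer has drifted beyond the mismatch budget is invisible
  to the scanner (but a curated gene interval can still be *classified*, see
  below, because classification only requires the `CAC`).

## Overlap resolution and determinism

Several openings can share one 3' RSS (an internal `AG` or `ATG` in the same
exon). Candidates sharing an RSS anchor on one strand are collapsed to the
one with the longest open leader — the smallest start — with the leader mode
as a deterministic tie-break; overlapping candidates on opposite strands are
both kept. Output is sorted by sequence, start, strand, so identical inputs
give byte-identical outputs.

## D segments

A D segment is a short sequence (default 8–25 nt) between a 12-RSS and a
23-RSS with at least one open reading frame; per-frame openness is recorded
in `notes` because D segments are used in all frames. The pattern is so weak
that genome-wide blind scanning is mostly noise — in practice D genes are
confirmed from expressed reads — so `scanDSegments()` requires an explicit
window and the CLI refuses blind D scans.

# Functionality classification

`classifyV()`/`classifyJ()` implement the IMGT-style rules with
machine-readable reasons:

* **P (pseudogene)**: a stop codon, a frameshift, or an RSS without the
  `CAC` motif.
* **ORF**: no P-defining defect, but some feature altered — a missing anchor
  or FG motif, a missing splice site, a failed signal-peptide prediction, or
  a sub-threshold external RSS score.
* **F (functional)**: nothing altered.

Two reason codes (`no_signal_peptide`, `rss_low_score`) can only fire when
the corresponding external hook is supplied; with hooks absent the defaults
are a permissive pass, which keeps default runs deterministic and offline.
Frameshift detection in the source protocol rests on expressed-read
evidence; without such evidence the code is not emitted (a
consensus-comparison heuristic would be possible but is deliberately not a
default). `evaluateVRegion()`/`evaluateJRegion()` compute every classifiable
feature for a *stated* interval, so curated or deliberately defective genes
can be classified even though the scanner would never emit them.

V gene boundaries run from the signal-peptide cleavage site — when an
external predictor provides one — to the base before the RSS `CAC`; the
fallbacks are the spliced-exon start or the `ATG` (`defineVBounds()`).

# Families, consensus and naming

V genes with at least 75% nucleotide identity form a family. Identity is
`percentIdentity()` below, rounded to one decimal before threshold
comparisons (matching the precision at which such identities are reported).
Clusters are seeded by single linkage at the threshold and refined: each
cluster's consensus is rebuilt and genes are reassigned to their
best-matching consensus, to a fixed point with bounded iterations. The
consensus comes from a center-star multiple alignment (center = member with
the greatest summed alignment score; deterministic tie-breaks) followed by
per-column plurality with alphabetic tie-break; majority-gap columns are
dropped. Genes below threshold against every consensus become singleton
families — unless listed in a waiver file, the escape hatch for documented
sub-threshold assignments (the precedent being a gene kept in its family at
73.8% identity). A waived gene joins its best family with its identity and a
waiver flag recorded.

Names follow the field's convention: `TR{A,B,G,D}V{family}-{k}`, with family
numbers and member numbers `k` ascending 5'→3' *toward the C gene* — i.e. by
descending forward-strand coordinate on a reverse-strand locus — and J genes
numbered `TR*J{k}` in the same order. Pseudogenes take a `p` prefix, ORFs an
`orf` prefix. Tentative family assignment from the 5' amino-acid motif table
(`V_FAMILY_MOTIFS`, e.g. TRAV1 `QVQQ`, TRGV3 `QAVPMQ`/`QAAPVQ`) is exact
match only within the first 15 mature residues (extended by an assumed
leader length, default 20 aa, for single-exon candidates whose protein still
carries the leader).

# The comparison formulas

Cross-annotation comparison uses a match-maximizing global alignment with
free gaps and no mismatch penalty, whose optimum equals the longest common
subsequence; it is computed by exact dynamic programming in C++ (sequences
are at most a few hundred nucleotides, so no banding or heuristics). Then

* `percent identity = identical positions / length of shorter sequence × 100`
* `mismatches = length of shorter sequence − identical positions`

Note the documented quirk of the shorter-length normalization: a sequence
that embeds completely into a longer one scores 100%. `bestMatchReport()`
excludes references below 223 nt (full-length V genes only) and reports
*all* references tied at the maximum identity, to one decimal.

# Repertoire statistics

All statistics are UMI-weighted. Clonotypes whose CDR3 contains a stop codon
or whose nucleotide CDR3 is untranslatable are excluded first, with a logged
count, mirroring the exclusion of non-expressed receptors. To compare
samples, each sample is downsampled without replacement at the UMI level to
the total of the smallest sample (seeded). The summaries are: V/J usage and
V–J pairing frequencies; the CDR3 spectratype (length distribution, whose
Gaussian-like shape centred near 14–15 residues indicates an unbiased
repertoire); rank-abundance shares at configurable rank boundaries (default
decades — the exact grouping behind published plots is shown only
graphically, so it is a config choice); publicity (the share of each
sample's repertoire occupied by clonotypes found in `k` of the samples,
"public" meaning all of them; the clonotype key defaults to V call + J call
+ CDR3 amino-acid sequence, with a nucleotide option, since either
convention appears in practice); convergence (distinct nucleotide sequences
per CDR3 amino-acid sequence); mean amino-acid counts per CDR3; and chimera
flagging — a V call from a different chain's locus than the table's chain,
the signature of trans-locus rearrangements such as Vα joined to δ D-J-C.

# The synthetic data generators

`simulateLocus()` plants V and J cassettes at recorded coordinates and
strands in i.i.d. background. Each V cassette is `[AG or ATG-leader][V exon
with the three anchors at fixed offsets][CAC + 23-spacer + nonamer]`; each J
cassette is the 12-RSS (reverse-complemented), a CDR3 stub, the J core with
the confirmatory motif, and a `GTAAGA` donor. Defects (stop codons, CAC
ablation, anchor/FG/donor mutations, out-of-tolerance spacers) are planted
per gene and recorded in the truth table, which suffices to score every
scanner, classifier and summary operation without external data.

Two construction choices make exact-coordinate recall a well-defined target
rather than a statistical one. First, planted V intervals sit at the
scanner's length-window maximum and J intervals at the window minimum, so an
alternate opening or donor reusing a planted RSS is excluded by the length
window or collapsed by the same-RSS rule. Second, after assembly the locus
is *certified*: every potential RSS anchor on either strand (a `CAC` with
the nonamer consensus at a tolerated offset) is enumerated and checked by an
independent, regex-based brute-force cassette test; if any non-planted
anchor admits a complete cassette the locus is rebuilt from a derived seed.
Random DNA contains a near-consensus nonamer roughly every 800 bp, so the
anchor enumeration alone would be hopeless as a rejection rule — the
brute-force confirmation is what makes certification both sound and cheap.

`simulateRepertoire()` emulates the statistical structure of an unbiased
splenic repertoire: three samples, 8,000 clonotypes each, UMI counts
`1 + Geometric(0.8)` so most clonotypes are singletons (about 10,000 UMIs
per sample), V/J usage weights drawn once from a seeded Gamma(2) and
recorded as truth, CDR3 lengths from a discretized normal centred at 14.5
residues (sd 1.5), a 10% planted public share, a 5% background convergence
rate plus one planted 12-way convergent CDR3, and an optional chimera rate
(0.22 emulates a δ-chain repertoire where every fourth to fifth receptor is
chimeric). Nucleotide CDR3s are drawn codon-consistently with the amino-acid
sequence.

What the generators do *not* emulate: real loci are shaped by duplication of
long homology units, so genes come in near-identical repeats with conserved
intergenic structure; real backgrounds are not i.i.d.; real repertoires have
power-law tails and shared convergent selection. Passing the synthetic tests
therefore demonstrates correctness of the algorithms under the stated model,
not field performance on a real assembly — the full-scale check against a
real genome is a separate, heavier exercise (see the acceptance notes in the
README).

# Numerical and design choices

* Coordinates: public containers are `GRanges` (1-based inclusive, the
  Bioconductor convention); GFF3 output is 1-based inclusive; MiXCR-style
  anchor offsets are 0-based within the exported gene, per that format.
  Low-level arithmetic converts at the boundary only.
* Lowercase (soft-masked) input is uppercased and scanned; masking is not a
  filter.
* Identity threshold comparisons use `≥` on values rounded to one decimal.
* Consensus ties break alphabetically; center selection ties break on the
  lexicographically smallest sequence, then name — all order-invariant.
* Downsampling and both simulators take explicit integer seeds and restore
  the caller's RNG state.
* Problem sizes in the test suite and acceptance script (50 loci of 5 V +
  4 J; 1,000 alignment pairs of length ≤ 12; 20 family seeds; 3 × ~10,000
  UMIs) were chosen as the smallest sizes at which each property is a sharp
  pass/fail rather than a noisy estimate.
* Degenerate inputs: empty FASTA yields an empty annotation bundle; empty
  clonotype tables are errors for statistics that would divide by zero;
  `revComp("")` is `""`.

# Known limitations

* No pseudogene *discovery*: pseudogenes lack the defining features the
  scanner keys on, and in the source protocol they were recovered from
  expressed-read alignments. The classifier can label them when given
  curated intervals.
* No L-PART1 reconstruction for spliced leaders; candidates carry the splice
  acceptor position only, and the signal-peptide decision is a hook.
* CDR1/CDR2/FR anchor offsets beyond the 2nd-CYS-derived CDR3 anchor are
  heuristic defaults meant to be overridden from an external domain
  alignment.
* The RSS model is a motif criterion; borderline RSSs need an external
  RIC-style scorer through `rssScoreHook`.
* `bestMatchReport()` is exact LCS, quadratic per pair: fine for gene-sized
  sequences, not for chromosomes.
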