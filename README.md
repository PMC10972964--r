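# vdjkit

Discovery and annotation of immune receptor V(D)J germline genes in genomic
DNA, plus post-clonotyping repertoire summary statistics — aimed at
immunogeneticists annotating T-cell (or B-cell) receptor loci in new genome
assemblies and analysing UMI-barcoded AIRR-style clonotype tables.

Antigen-receptor gene segments are defined less by overall conservation than
by a grammar of features. `vdjkit` scans both strands of genomic DNA for
intervals that satisfy that grammar:

* **V genes** — a leader opening (in-frame `ATG` for single-exon leaders, or
  an `AG` splice acceptor for spliced leaders), an open reading frame
  carrying the conserved V-domain anchors (1st-CYS, CONSERVED-TRP, and the
  2nd-CYS motif `YYC/YFC/YLC/YHC/YIC/TFC`), ending at a 3' recombination
  signal sequence (RSS) with a 23 ± 1-nt spacer whose heptamer begins `CAC`;
* **J genes** — a 5' 12 ± 1-spacer RSS, the J core `TTYGGNNNNGG` translating
  the conserved `FG`, the confirmatory `TNNBNRT` motif, no stop codon, and a
  3' `GTRDGD` splice donor;
* **D segments** — short open sequences between a 12-RSS and a 23-RSS,
  scanned only inside a user-supplied window.

Candidates are classified IMGT-style as functional (**F**), open reading
frame (**ORF**, an altered feature without stops) or pseudogene (**P**,
stop/frameshift/CAC-less RSS) with machine-readable reasons; V genes are
clustered into families at ≥ 75% nucleotide identity to an iteratively
refined family consensus; genes are named `TR{A,B,G,D}V{family}-{k}` /
`TR*J{k}` in ascending order 5'→3' toward the C gene (`p`/`orf` prefixes for
P/ORF); and F + ORF genes export as a germline library with MiXCR-style
anchor points. Cross-annotation comparison uses a match-maximizing global
alignment (free gaps, no mismatch penalty — the optimum equals the longest
common subsequence) with

```
percent identity = identical positions / length of shorter sequence × 100
mismatches      = length of shorter sequence − identical positions
```

Repertoire statistics from clonotype tables (sample, chain, V/J calls, CDR3
nt/aa, UMI count) are UMI-weighted throughout: V/J usage and pairing, CDR3
spectratype, rank-abundance shares, publicity across samples, CDR3
convergence, amino-acid composition and chimeric-receptor detection, after
excluding non-expressed clonotypes and optional downsampling to the smallest
sample. Seeded simulators generate ground-truthed synthetic loci (with
optional planted defects) and repertoires, so the whole pipeline is testable
offline.

## Worked example

```r
library(vdjkit)

loc <- simulateLocus(locusSpec(seed = 42))   # 5 V + 4 J planted genes
gs  <- runAnnotate(loc$seq, chain = "TRA", towardC = "left")
gs
#> GermlineSet (TRA)
#>   candidates: 5 V, 4 J
#>   functionality: 9 F / 0 ORF / 0 P
#>   V families: 5

data.frame(name = geneNames(gs), call = functionality(gs)$call,
           start = GenomicRanges::start(candidates(gs)),
           end   = GenomicRanges::end(candidates(gs)))
#>      name call start  end
#> 1 TRAV5-1    F   334  693
#> 2 TRAV4-1    F  1034 1393
#> 3 TRAV3-1    F  1738 2097
#> 4 TRAV2-1    F  2396 2755
#> 5 TRAV1-1    F  3052 3411
#> 6   TRAJ4    F  3723 3762
#> 7   TRAJ3    F  4129 4168
#> 8   TRAJ2    F  4615 4654
#> 9   TRAJ1    F  4998 5037
```

All nine planted genes are recovered at their exact coordinates and
classified functional; the locus is reverse-strand-dominant, so member
numbers ascend toward the C gene on the left (decreasing coordinate). The
comparison formulas, on a toy pair:

```r
percentIdentity("ACGT", "AGT")   # 100 — AGT embeds completely in ACGT,
mismatches("ACGT", "AGT")        # 0     the shorter-length normalization
```

Repertoire summary of a simulated three-bird spleen dataset:

```r
rep <- simulateRepertoire(repertoireSpec(seed = 5))
rs  <- repertoireSummary(rep$tables, downsample = TRUE, seed = 5)
rs
#> RepertoireSummary (TRA)
#>   clonotypes: 23966 (0 excluded as non-expressed)
#>   V genes: 12; J genes: 6
#>   CDR3 spectratype mode: 14 aa
#>   public share (all samples): 0.101
#>   max CDR3 convergence: 12
#>   chimera rate: 0.000
```

The planted structure — a Gaussian-like spectratype centred at 14–15
residues, a 10% public share, a 12-way convergent CDR3 — is recovered from
the tables alone.

A thin command-line wrapper ships in `inst/cli/vdjkit` with subcommands
`find`, `annotate`, `compare`, `repertoire`, `simulate` and
`export-germline`, e.g.

```sh
Rscript inst/cli/vdjkit simulate locus --seed 42 --out sim/
Rscript inst/cli/vdjkit annotate --fasta sim/locus.fasta \
        --chain TRA --toward-c left --out annotation/
```

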