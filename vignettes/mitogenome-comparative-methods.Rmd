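---
title: "Comparative mitogenome analysis with mitocomp: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenome analysis with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## Scope and data model

`mitocomp` analyses annotated circular mitochondrial genomes of the
typical vertebrate layout: 13 protein-coding genes (PCGs), 22 tRNAs, two
rRNAs and one non-coding control region (CR), distributed over the heavy
(H) and light (L) strands.  The central container, `mito_genome`, holds an
ordered feature table (1-based inclusive coordinates; an origin-spanning
feature such as a CR annotated `15565..16796 + 1..58` is stored as two
segments, never as `end < start`) plus an optional H-strand genome
sequence.  Because the sequence is optional, all gene-table arithmetic
(lengths, overlaps, spacers, strand tallies) runs on a coordinate table
alone; codon-level analyses require the sequence.

The package ships the transcribed annotation of the black softshell
turtle (*Nilssonia nigricans*) mitogenome (16,796 bp, GenBank MG383833)
as its reference fixture, available via `nilssonia_feature_table()`.
Gene lengths are always recomputed from coordinates rather than trusted
from any size column; on this annotation the circular coverage identity
closes exactly: 16,685 bp of features + 124 bp of spacers − 13 bp of
overlaps = 16,796 bp.

## Composition and strand skew

`compute_composition()` reports base counts, A+T percentage over
unambiguous bases, and the strand skews

    AT skew = (A − T) / (A + T),   GC skew = (G − C) / (G + C).

`partition_composition()` pools features into genome / PCG / tRNA / rRNA /
CR partitions.  Following the field's convention, L-strand PCGs are
reverse-complemented into reading orientation before pooling, while tRNA
and rRNA genes are pooled in the genome register.  Ambiguous bases are
excluded from skew denominators and from the A+T percentage (the
convention is not universal; this choice is documented rather than
assumed silent).

## Relative synonymous codon usage

Codon counting (`count_codons()`) reads each CDS in frame from its first
base, drops a trailing 1–2 nt incomplete stop, tallies stop codons
separately and skips codons containing ambiguity codes (with a count).
The genetic code is fixed to the vertebrate mitochondrial code
(`transl_table` 2: AGA/AGG are stops, ATA is Met, TGA is Trp), embedded
via `Biostrings::getGeneticCode("2")`.  RSCU for codon *j* of amino acid
*i* with *n~i~* synonymous codons is

    RSCU_ij = x_ij / ( (1/n_i) * sum_j x_ij ),

so each family sums to its size and equal usage gives RSCU 1.  Stop
codons are excluded from RSCU, matching the common MEGA convention.

## tRNA cloverleaf folding

`fold_cloverleaf()` performs an exhaustive, deterministic search over a
constrained cloverleaf grammar rather than thermodynamic folding: the
acceptor stem may take 6–8 pairs, the DHU arm is absent or has a 3–4 pair
stem with a 4–12 nt loop, the anticodon stem has 4–6 pairs with the
canonical 7 nt loop, the variable loop spans 3–23 nt and the T-arm has a
4–5 pair stem with a 4–9 nt loop.  Every admissible decomposition is
scored `2·WC + 1·wobble − 1·mismatch` over its stem pairs, in the DNA
register (so the wobble pair is G·T).  Ties break toward the canonical
(7,4,5,5) arm sizes, then the smallest variable loop, making folds
reproducible.  A decomposition is admissible only if no single stem
carries more than one mismatch (`max_mismatch_per_arm`); sequences
without complementary stems — and tRNAs whose arms degenerated beyond
recognition — return an explicit "unfoldable" result.  The decomposition
covers every input position exactly once, so `flatten_cloverleaf()` is an
exact inverse.  `compare_across_species()` summarises one tRNA across
genomes (arm-length ranges, pooled pair-class tallies, modal-profile
counts) and flags tRNAs accumulating ≥ 10 non-Watson-Crick pairs across
the set, the working definition of "highly variable" used in comparative
tRNA surveys.

## Control region

Tandem repeats are found by an exact scan (`find_tandem_repeats()`): for
each period *p* up to 60 bp, maximal runs where `s[i] == s[i+p]` are
extended greedily; a run reports the locus motif, the smallest admissible
period (a run of `(AT)xN` is never reported with period 4) and a possibly
fractional copy number.  Overlapping candidates collapse to the
leftmost-longest locus.  A `min_length` floor (default 8 bp) suppresses
the chance mono- and dinucleotide doublets that saturate random sequence;
alignment-scored (mismatch-tolerant) repeats in the style of Tandem
Repeats Finder are deliberately out of scope because the repeats of
interest here are exact.  Conserved motifs (e.g. the CSB-1 block's
5'-GACATA-3') are located IUPAC-aware via `scan_motif()`.  Candidate
stem-loops use a max-pairing heuristic (`find_stem_loops()`): contiguous
stems of Watson-Crick/wobble pairs within 2–7 pairs around loops of 4–23
nt, locally maximal, ranked by stem length then fewest wobbles — a
deliberate simplification of free-energy folding that keeps results
deterministic and dependency-free.

## Ka/Ks (Nei–Gojobori 1986)

`ng86()` implements the counting method with Jukes–Cantor correction.
Synonymous sites per codon are the summed fractions of single-base
changes that preserve the amino acid, with changes *to stop codons
excluded from the denominators*; sites are averaged over the two
sequences.  Observed differences for codons differing at 2–3 positions
are averaged over all substitution orderings whose intermediates avoid
stops (if every ordering is blocked, all orderings are used and stop
steps count as nonsynonymous) — the DnaSP-compatible choice.  Proportions
are corrected by `d = −(3/4)·ln(1 − 4p/3)`; `p ≥ 3/4` yields an explicit
saturated (NA) rate, and the Ka/Ks ratio is NA when Ks = 0.  Codon
columns containing gaps, ambiguity or stops are excluded pairwise, not
list-wise.  The implementation is validated against an independent
brute-force enumerator over all 61 × 61 stop-free codon pairs.

Pairwise codon alignment (`align_codons_pairwise()`) is protein-guided:
sequences are translated, globally aligned (match +1, mismatch 0, gap −1,
via `Biostrings::pairwiseAlignment`) and back-mapped so gaps occur only in
whole-codon units.  Per-gene summaries interpret the "±" of comparative
tables as the standard deviation across pairwise comparisons, exclude
undefined ratios with an explicit count, and rank genes by ascending mean
ratio.  Because the exact comparison set in published tables is often
ambiguous, `kaks_table()` offers both one-vs-reference and all-pairs
modes without asserting either as canonical.

## Distances and tree

The phylogeny stage is intentionally lightweight: Kimura two-parameter
distances on the concatenated PCG supermatrix and a Saitou–Nei
neighbor-joining tree (via `ape::nj`, with negative branches clamped to
zero under a warning).  This replaces, and does not emulate, a model-
selected maximum-likelihood analysis with bootstrap; topology claims are
therefore limited to what NJ guarantees — exact recovery of additive
distance matrices, which the test suite verifies on random 5–8 taxon
trees.  Genes whose aligned lengths differ across inputs are skipped by
the pipeline's tree stage with a log note (a full multiple-sequence
aligner is out of scope; generator output and curated equal-length sets
concatenate directly).

## The synthetic genome generator

`generate_genome()` emits a complete annotated 16,796 bp circular genome
with the reference layout and a truth record, deterministic in
`(spec, seed)` and leaving the caller's RNG untouched.  Its defaults are
the study conditions the package is tested under:

* per-partition A+T and skew targets equal to the published values for
  the reference genome (genome 62.16 % A+T; PCG 61.26 %, AT skew 0.136,
  GC skew −0.414; tRNA 63.82 %; rRNA 61.47 %; CR 68.52 %);
* CDS built codon-wise: templated start codons (ATG/ATA/ATT/ATC),
  non-stop bodies, frame-determined complete (TAA/AGA) or incomplete
  (T/TA) stops.  Codon sampling weights are fixed-point corrected so the
  expected base composition still meets the target despite the exclusion
  of stop codons;
* tRNAs realised from the cloverleaf grammar (canonical 7/4/5/5 arms,
  trnS1 without a DHU arm, anticodons from the annotation, 3' stem sides
  complementary to the 5' draws), re-validated by folding before
  acceptance;
* a control region carrying the four tandem repeats (ATTAT)×8, a random
  49 bp duplication, (AT)×7 and (TATTA)×20 with 151/781/87 bp spacers, a
  planted GACATA motif, and junction guards so flanking sequence cannot
  extend a planted run; planted repeats are re-validated with the
  repeat finder before the genome is returned.

Annotated gene overlaps are honoured by writing features first-writer-
wins in the order tRNA → PCG → rRNA → CR.  Consequently the two PCGs
whose starts sit inside an upstream gene (atp6, nad4) may not realise
their templated start codons — the same ambiguity real overlapping
annotations carry — and validation of codon templates is restricted to
non-overlapped genes.

What the generator does *not* emulate: phylogenetically correlated
sequence evolution (divergent CDS pairs are pairwise only), codon-usage
structure beyond base composition, rRNA secondary structure, and
mismatch-containing ("near-exact") tandem repeats.  Passing truth-
recovery tests therefore demonstrates correctness of the measurement
code under the stated statistical structure, not performance on real
genomes with features outside that structure.

### Tolerances

The generator's documented composition tolerance is ±0.01 A+T fraction
at genome scale (n = 16,796).  Small partitions fluctuate more: binomial
noise is `sqrt(p(1−p)/n)`, and tRNA stems double the variance because
each 3' base mirrors its 5' partner, so tests allow ~3 standard
deviations per partition (PCG ±0.015, CR ±0.04, tRNA ±0.05).  Genome-wide
strand skew is *emergent* rather than enforced: the published partition
skews, length-weighted, imply a genome AT skew near 0.16, which is what
genomes built to the partition targets realise; the package asserts the
sign and the partition-level magnitudes instead of forcing the printed
genome-wide figure, and this discrepancy among the printed values is
surfaced here rather than hidden.

`generate_divergent_pair()` plants at most one substitution per codon
(synonymous with probability `syn_rate` per site, nonsynonymous with
`nonsyn_rate`), so realized substitution counts coincide exactly with
NG86 observed differences — the truth record is exact, not approximate.
Rates are capped below 0.5 to stay clear of the Jukes–Cantor saturation
boundary.

## Reproducibility choices

All randomness flows through a single integer seed; generation restores
the caller's `.Random.seed`.  Folding, repeat collapse, alignment and NJ
all carry explicit deterministic tie-breaks, so identical inputs give
byte-identical artifacts (the pipeline log carries the only timestamps).
Problem sizes used by the test suite and the acceptance script — one
full synthetic genome per check, 20 random trees, 25 planted repeat
fixtures, 50 divergence replicates at 100 codons — were chosen as the
smallest sets at which the binomial uncertainty of each recovery rate is
well below the asserted thresholds.

## A worked example

```{r example, eval = FALSE}
rec <- nilssonia_feature_table()
adjacency_analysis(rec)$summary
#> 6 overlaps (13 bp), 19 spacers (124 bp), longest 33 bp

gen <- generate_genome(seed = 1)
partition_composition(gen$record)$genome
#> <composition> 16796 bp  A+T 62.41%  AT skew 0.130  GC skew -0.290

ng86(align_codons_pairwise("ATGGCTAAA", "ATGGCCAAA"))
#> <kaks> S=1.67 N=7.33 Sd=1.00 Nd=0.00 Ks=1.2071 Ka=0.0000 Ka/Ks=0.0000 (3 codons)
```

## Known limitations

GenBank parsing covers the flat-file subset the package writes (LOCUS,
ACCESSION, ORGANISM, gene/CDS/tRNA/rRNA/D-loop features with
`complement()` and two-segment `join()` locations); richly qualified
records from other pipelines may need the TSV route.  The CR analysis
does not delineate TAS/CD/CSB domains (located by manual alignment in
comparative studies); only the CSB-1 motif scan is provided.  Stop-codon
annotation conventions that conflict with frame arithmetic (single-base
"stops" on frame-complete genes) are reported as computed, with the
annotated value flagged, rather than silently reconciled.
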