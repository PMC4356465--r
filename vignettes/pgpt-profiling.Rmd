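---
title: "Profiling plant-growth-promoting-trait genes in shotgun metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling plant-growth-promoting-trait genes in shotgun metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgptProfiler)
```

# Overview

`pgptProfiler` turns unassembled shotgun metagenome reads and their
tabular homology-search results into a functional profile of
plant-growth-promoting-trait (PGPT) genes: which trait genes a
root-associated community carries, at what depth- and length-normalized
abundance, and in which taxa. The package operates strictly downstream
of the searches themselves: its inputs are reads (FASTA), 12-column
tabular hit tables, a curated gene catalog with representative lengths,
and a subject-to-lineage map.

# The screening model

Every assignment in the pipeline rests on one rule: the **best hit** of
a read is the alignment with maximal bit score, ties broken by minimal
E-value, then by lexicographically smallest subject id. The last
tie-break carries no biological information — it exists to make every
result reproducible to the byte regardless of input order.

Three screens are applied:

* **Host filter.** Plant compartments contaminate bacterial extracts
  with host DNA. A read is removed iff its best nucleotide-vs-nucleotide
  hit, among hits with E-value strictly below $10^{-10}$, resolves to a
  lineage containing the host clade label (default `Streptophyta`) at
  *any* rank — the label names a clade, not a rank, so matching is
  rank-agnostic. Reads with no qualifying hit are kept: the filter is
  deliberately conservative, since an over-aggressive host filter biases
  every downstream frequency.
* **Primary protein screen.** Translated-query hits against the protein
  database survive at E-value $< 10^{-10}$, strictly. The boundary value
  is rejected; all thresholds in the package are strict inequalities, so
  that each cutoff has exactly one unambiguous reading.
* **Protein-query re-screen.** Gene families that a classification of
  the primary search misses (in the motivating use case: nitrogenase,
  *pqqC*, methanol dehydrogenase) are re-screened with a protein query
  against translated reads, surviving at E $< 10^{-10}$, alignment span
  $> 250$ bp and identity $> 40\%$. The span threshold is stated in bp
  for an amino-acid-level alignment; the only unit-consistent reading is
  aligned columns $\times 3$, which is what the package implements. The
  two screens are kept as separate operations with independent
  thresholds because the length/identity minima are documented only for
  the re-screen.

Each read then counts toward at most one catalog gene — the gene of its
best surviving hit — because multi-counting a read across genes would
inflate every frequency it touches.

# The detection-frequency statistic

For gene $g$ with representative length $L_g$ (kbp) detected in $n_g$
reads of a sample with $N$ total reads,

$$F_g = \frac{n_g}{L_g} \cdot \frac{100{,}000}{N}.$$

Dividing by $L_g$ removes the trivial advantage of long genes (a long
gene intercepts proportionally more shotgun reads); rescaling by
$10^5/N$ makes samples of different depth comparable. The statistic is
linear in $n_g$ and inversely proportional to both $L_g$ and $N$, and
$F = n$ exactly at $L = 1$ kbp, $N = 10^5$ — identities the test suite
asserts. Gene lengths are catalog inputs (deduced from UniRef cluster
representatives), never estimated from the reads.

Two conventions deserve note:

* **Denominator.** $N$ defaults to the sample's *raw* total read count,
  before host filtering, matching the usual reporting of per-sample
  totals; since host contamination is ~2%, the choice moves frequencies
  by ~2%. A `freqDenominator = "hostFiltered"` flag switches to
  post-filter totals.
* **Aggregation.** Frequencies are computed per sample from that
  sample's own $N$, then summarized as mean ± SD across samples, with
  the sample SD ($n-1$ denominator) — the conventional reading of a
  "mean ± SD ($n = 3$)" summary. Category totals sum the *unrounded*
  member frequencies per sample and only then aggregate; member SDs are
  never summed (SDs are not additive).

For display, values $\ge 1$ are rounded to the nearest integer and
values $< 1$ to one decimal, both half-away-from-zero (base R's
`round()` is half-to-even, which would turn 2.5 into 2); genes with no
read in any sample render as "ND". The unrounded table is always
emitted alongside, because rounded category rows cannot be recomputed
from rounded members.

# Taxonomy

Each hit-bearing read takes the lineage of its best surviving hit.
Relative abundance at a rank is the percentage of *assigned* reads —
unassigned reads cannot meaningfully sit in the denominator of a
taxonomic percentage — and a read contributes at a rank only if its
lineage names that rank. The top `nMajor` taxa by mean percentage
(default 3, ties alphabetical) are listed and the remainder pooled into
"Others", so unrounded per-sample percentages sum to exactly 100.
Lineages are restricted to the five ranks phylum–genus.

Rarefaction is plain Monte-Carlo subsampling without replacement,
seeded and therefore reproducible. The closed-form hypergeometric
expectation
$E[S(d)] = \sum_i \left(1 - \binom{N - N_i}{d}\big/\binom{N}{d}\right)$
is exported (`expectedRichness`) and used in the tests as an
independent oracle; the Monte-Carlo curve must match it within three
standard errors at every depth and equal observed richness exactly at
full depth.

# Methanol-dehydrogenase typing

The two methanol dehydrogenase types, lanthanide-dependent *xoxF* and
calcium-dependent *mxaF*, are too similar for a plain similarity call,
so typing is phylogenetic. Short environmental fragments are mutually
near-random, which makes a joint tree over all queries unresolvable;
the package therefore places **one query at a time** on a tree with all
references and outgroups (a joint mode would be a trivial extension but
is not what the procedure calls for).

Distances are uncorrected p-distances with pairwise deletion of gapped
columns — the simplest defensible metric when only relative placement
matters; a Poisson correction is available behind a flag for more
divergent sets. Trees are built with a canonical Saitou–Nei
neighbor-joining implementation: the pair minimizing
$Q(i,j) = (n-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$ is joined at
each step, branch lengths follow the standard formulas with negative
estimates clamped to zero (clade logic needs nonnegative lengths), and
Q-ties are broken by the lexicographically smallest pair of
representative leaf labels, which makes topology and calls invariant
under permutation of input order. On any additive matrix the
implementation reproduces the generating tree's path lengths exactly
(to floating point), which the tests verify against 100 random trees
and against `ape::nj` as an independent cross-check.

The call itself operationalizes "clusters with": root on the outgroup
(on the edge above the outgroup clade when there are several outgroup
leaves), walk upward from the query tip, and let the first clade
containing any other labelled leaf decide — all-xoxF references call
*xoxF*, all-mxaF call *mxaF*, and a clade containing an outgroup leaf
or both reference types is *undetermined*. A query identical to a
reference is always called that reference's type; a random sequence
attaches basally and is called undetermined.

# The isotope test

Whether ¹⁵N₂ exposure shifted the δ¹⁵N (‰) signature of plant tissue is
judged by a two-sided two-sample t-test, from replicates or directly
from summary statistics. Welch's variant is the default — with $n = 3$
per group and visibly unequal SDs, assuming equal variances is the
stronger assumption — and the pooled-variance Student variant is
selectable; for the motivating comparison both land far from the
threshold, so the choice does not affect the conclusion. Significance
requires $p < 0.05$ strictly. The degenerate zero-variance case is
defined explicitly: equal means give $p = 1$, unequal means are an
error rather than a silent infinity.

# The synthetic-data generator

The generator exists so that every downstream stage is testable with
known truth. Its defaults encode the study design the pipeline was
built for: 3 composite samples, 60,000 reads per sample (the scale of a
one-region pyrosequencing run, within the observed 46k–80k range), mean
read length 645 bp with SD 130 bp (a typical long-read pyrosequencing
spread) truncated to [100, 1200] bp, 2% host-origin reads, and a 54%
protein-database hit rate. Gene abundance weights default to equal over
eight named PGPT genes and genus weights to six root-associated genera
in roughly the proportions seen in taproot communities — both are free
parameters of the simulation, not calibrated to any observed frequency
table, because true per-gene abundances are unobservable in the real
data.

Structurally, the generator guarantees exactly the properties the
pipeline assumes: each gene-origin read's true-origin hit has the
minimal E-value among its hits, decoy hits are strictly worse in both
E-value and bit score, bit scores decrease strictly in E-value within a
read, and host reads hit only the host subject. Every draw flows from
one integer seed (with fixed offsets per stage), so identical configs
give byte-identical outputs.

What the generator does *not* emulate: sequencing error models
(homopolymer errors, chimeras), realistic amino-acid evolution, a
nonzero rate of truly mis-leading best hits, or an unannotated
"background" read class. Consequently, passing recovery tests
demonstrates that the screening, counting and normalization chain is
correct — not that the thresholds would perform identically against a
real, noisy reference database.

# Numerical and edge-case conventions

* Average read length per sample is the **floor** of total bp over
  total reads, applied identically to per-sample and pooled rows.
* Tabular hit files must have exactly 12 columns; extra columns are an
  error rather than silently ignored, since truncation usually means an
  upstream export was misconfigured. Coordinates stay 1-based inclusive
  as in the source format.
* FASTA read ids are the first whitespace-delimited token of the
  header; duplicate ids and sequences before any header are rejected
  with line numbers.
* Newick output fixes branch lengths at six decimals, so round-trips
  are exact for lengths already at that precision and within
  $5\times10^{-7}$ per branch otherwise.
* `relativeAbundance` and `aggregateSamples` refuse fewer than two
  samples (an SD over one value is undefined); `rarefactionCurve`
  refuses depths beyond the assigned-read count.

# Problem sizes in the test suite

The acceptance-style tests run the full synthetic pipeline at 3 × 20,000
reads (large enough that 3-SD binomial and multinomial recovery bounds
are tight at the default rates), neighbor joining on 100 random
additive matrices of 4–12 taxa, MDH typing on 40 queries per scenario,
rarefaction at 500 replicates per depth, and 10,000 null replicates for
the t-test's type-I error — sizes chosen so the whole suite completes
in well under a minute while keeping every statistical bound at three
standard errors.

# Known limitations

* The package never runs BLAST-family searches, MEGAN-style binning or
  multiple alignment; all are consumed as inputs.
* Lineages are capped at genus; species-level calls and LCA-style
  (lowest common ancestor) assignment are out of scope — best-hit
  assignment is simpler and is what the profiling procedure specifies,
  but it is known to overclaim precision for reads whose top hits are
  taxonomically mixed.
* Representative gene lengths come from a catalog; if a community's
  actual gene lengths deviate systematically, frequencies inherit that
  bias.
* The MDH clade rule is an operationalization of visual "clustering";
  bootstrap support is not computed, so single-read calls near the
  rule's boundaries should be treated as provisional.
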