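---
title: "Methods behind stressmir: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind stressmir: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressmir)
```

`stressmir` re-implements a classic three-library plant small-RNA analysis
(control, drought, salt) for species without a finished genome. This
vignette documents the statistical models and sequence rules the package
uses, the tunable parameters with their defaults and rationale, what the
synthetic-data generator does and does not emulate, and the design choices
made where the procedure was genuinely open.

## Library processing

**Cleaning.** The 3' adapter is removed at its leftmost full occurrence;
reads where the sequencer ran out of adapter keep a terminal partial match
of at least 6 nt. After trimming, reads are dropped if the insert is
outside 18–30 nt (the biologically meaningful small-RNA window; untrimmed
reads at the 36-nt machine length fall out here), contains `N`, or carries
any base below the quality floor. "Low quality" is rarely defined
precisely in study write-ups; the package's concrete rule is *any base
below Phred 20 after trimming* (`quality_floor = 20`). It is deliberately
simple, and the synthetic generator writes sequencing errors at Phred 10
exactly so this filter has observable work to do.

**Categorization.** Contaminant assignment is exact substring containment
in a user-supplied catalog (rRNA, tRNA, snRNA, snoRNA, repeat), applied
*before* miRNA assignment — a read matching both a tRNA and a known miRNA
is excluded as tRNA. Ties between contaminant classes resolve in the fixed
order rRNA > tRNA > snRNA > snoRNA > repeat. Exact containment (rather
than a heuristic short-read BLAST) makes the rule reproducible without an
external aligner; the contract is containment, not a particular tool.

**Conserved reads.** A read is conserved if its distance to some known
miRNA is at most 3, where distance is the Hamming distance at the best
ungapped offset alignment. Gaps are not modeled (the rule is stated in
mismatches). One genuine ambiguity: when read and catalog entry have
different lengths, whose overhang counts? The package counts *read-side*
overhang as mismatches and entry-side overhang as free, so a read fully
contained in a longer catalog mature at zero mismatches is conserved at
distance 0 — the only reading under which exact sub-reads of a known
mature stay conserved. Ties break by lower distance, then lexicographic
catalog id.

**Similarity.** Library similarity is the Jaccard index over each
library's 5 000 most abundant unique reads, in percent. Ties at the
abundance cutoff are broken lexicographically by sequence so the top set
is deterministic.

## miRNA discovery

**Candidates.** Reads with at least 3 counts in at least one library
(guarding against sequencing errors), an exact reference match, and no
contaminant class.

**Folding.** Each candidate is folded inside a 200-nt window placed with a
20-nt flank on the read's 5' side, plus the mirrored window; whichever
evaluates better is kept. The structure criterion is base-pair
maximization over Watson–Crick pairs plus G:U, with a minimum loop of 3
unpaired bases, computed by an `O(n³)` dynamic program in C++. Among
maximal structures the DP minimizes the summed distance of paired
positions from the window center, which makes the traceback deterministic
and biases ties toward centrally placed stems. Base-pair maximization was
chosen over thermodynamic folding because it admits an exact brute-force
oracle (the test suite enumerates all nested structures for windows up to
12 nt and checks equality), at the cost of noisier structures in random
flanks — which the locus evaluation below is designed to absorb.

**Locus evaluation.** A candidate read is accepted as a mature miRNA when

1. at least 60% of its positions pair onto one arm (`min_paired_frac`),
2. it lies wholly on that arm — if more than 20% of its positions pair
   within the read itself, it spans the terminal loop and is rejected;
   occasional stray pairings to the minority side are treated as noise of
   the maximum-pairing structure, not arm evidence,
3. the duplex asymmetry within the largest consistent stem segment is at
   most 4 nt (`max_bulge`); stray pairs implying larger jumps are dropped
   from the stem rather than poisoning it,
4. the star, derived from the duplex geometry with 2-nt 3' overhangs on
   both ends (star spans `partner(mature 3' end − 2) … partner(mature 5'
   end) + 2`), does not overlap the mature.

Star read support is counted from collapsed reads that are substrings of
the star region extended by 3 nt on each side, with lengths within 4 nt of
the mature. An exact-sequence star lookup proved brittle: in a noisy
200-nt window the maximum-pairing structure can shift the inferred star by
a nucleotide or two, and the window-based count (as miRDeep-style tools
use) is robust to that without ever inventing support — the non-overlap
rule in (4) guarantees the mature's own reads cannot count as star
evidence.

**Novelty, redundancy, families, clusters.** Conserved loci need no star
(well-known miRNAs often lack a sequenced star). Novel loci require at
least one star read, by default in the *same* library as the mature — the
stricter of the two readings of "co-exist in at least one library"; the
looser any-library reading is available as `same_library = FALSE`.
Precursors at least 95% identical over the shorter length (ungapped
sliding alignment, inclusive threshold) merge by single linkage, keeping
the locus with the highest summed mature count. Conserved loci inherit
their catalog family; novel matures cluster into families by single
linkage at ≤ 3 mismatches and are named `ghr-n1`, `ghr-n2`, … in
discovery order. Genomic clusters are maximal runs of ≥ 2 loci on one
contig with consecutive start gaps at most 10 kb — the distance is a
convention (no standard definition exists) and is exposed as
`cluster_distance`.

## Differential expression

Counts are normalized to reads per million (RPM = count / library total ×
10⁶) against the *clean-read* total of each library — the same
denominator the χ² contingency table uses, keeping the test and the
normalization consistent. Zero RPM values are adjusted to 0.01 (the
adjustment applies to the normalized value, not the raw count, and only to
exact zeros — small positives are never floored). The fold change is
log₂(treatment 1 / treatment 2), which makes the algebra exactly
antisymmetric and transitive: FC(D,C) + FC(S,D) = FC(S,C) to machine
precision, a property the tests assert at 10⁻¹².

Significance is Pearson's χ² without continuity correction on the 2×2
table `[[c₁, t₁−c₁], [c₂, t₂−c₂]]`, df = 1; a feature with zero counts in
both libraries is flagged not-testable (statistic 0, p = 1, fold change
0). The two-tier call is `**` when |FC| ≥ 1 and p ≤ 0.01, `*` when
|FC| ≥ 1 and 0.01 < p ≤ 0.05, `ns` otherwise, with all boundaries
inclusive exactly as stated. No multiple-testing adjustment feeds the
tiers — that is faithful to the fixed-cutoff scheme being reproduced — but
a Benjamini–Hochberg column is emitted alongside for modern use. At
single-library-per-condition depth the χ² p-values answer "is this
difference larger than sampling noise at this depth", not "is this effect
biologically reproducible"; the tier rule's |FC| ≥ 1 requirement is what
keeps trivially significant tiny effects out.

Family-level expression sums member raw counts before normalization (the
only order-independent aggregation). Presence/absence partitions
(`venn_partition()`) use raw count > 0.

## Target prediction and degradome validation

Plant miRNA targets are near-perfectly complementary, so scoring is
ungapped and positional: per miRNA position (5'→3'), a Watson–Crick pair
costs 0, a G:U wobble 0.5, a mismatch 1, and penalties double at positions
2–13 (the seed-proximal and cleavage region). Sites keep score ≤ 4, at
most 2 consecutive mismatches, and at most 1 mismatch within positions
2–13. These constants follow standard plant target-prediction practice and
are all exposed as arguments; scanning is vectorized over every window and
verified in tests against exhaustive per-window scoring.

Cleavage happens between the nucleotides facing miRNA positions 10 and 11;
the package's coordinate convention is that the transcript base paired to
position 10 is the first nucleotide of the 3' fragment (`site_end − 9`),
i.e. the expected 5' end of degradome tags. Validation requires strict
Watson–Crick matches at positions 10 and 11 (a wobble does not qualify)
and significance of the tag pileup: the upper-tail binomial probability of
at least the observed tag count at one position, given the transcript's
total tags and a uniform per-position null (1 / transcript length). This
explicit null replaces tool-internal category heuristics because it is
calibratable: under uniform tags the validated fraction sits at or just
below the nominal 5% (the binomial tail is discrete and therefore
conservative), which both the test suite and the acceptance script
measure.

## CitationRank

Genes mentioned in a document corpus are first filtered by species label,
then clustered into homolog families by single-linkage connected
components over a pairwise similarity table (threshold inclusive; cluster
ids are the smallest member gene id, making them deterministic). The
co-existence matrix counts documents mentioning members of both clusters
off the diagonal and each cluster's document frequency on the diagonal.

The rank itself is a damped power iteration: with prior `r₀` = document
frequencies normalized to sum 1 and `T` the column-normalized off-diagonal
co-existence matrix (zero columns replaced by the prior),

> r ← d · T · r + (1 − d) · r₀,  d = 0.85

run up to 1 000 iterations with early stop when the L1 change drops below
10⁻¹² (recorded in the result). The damping constant and the
frequency-based teleportation follow PageRank-family convention — the
frequency prior encodes "a frequently mentioned gene is important, and
co-mention with important genes propagates importance". Both are
arguments, since the source procedure fixes only the iteration count.
Scores sum to 1 at every step; tests check the fixed point against an
independent dense power iteration, permutation equivariance, and that
adding a co-mention edge never lowers the touched cluster's score.

Target linkage replaces an external translated-BLAST step with a pluggable
similarity function whose default is shared 8-mer identity (fraction of
the first sequence's 8-mers present in the second, edge threshold 0.1,
strict). The threshold semantics — "some member gene is sequence-similar
to a predicted target's transcript" — are preserved; the E-value scale of
an external aligner is not reproduced.

## The synthetic-data generator

Every input of the pipeline is generated from one `synthetic_config()`
with planted ground truth, so all claims above are testable offline. The
defaults emulate the three-library study design at desk scale:

* three libraries of 10⁵ reads (the real design runs 16–19 M; desk scale
  keeps the full pipeline under a couple of minutes on one CPU — the
  acceptance script uses exactly these sizes),
* 12 conserved and 8 novel miRNA loci planted as perfect-stem hairpins
  (21-nt mature, 12-nt loop, 6-nt flanks) in 12 contigs of 50 kb; the
  first three loci share a contig so a genomic cluster exists by
  construction,
* planted log₂ fold changes of ±2 on a handful of well-expressed miRNAs
  (the default effect plan), null elsewhere; per-condition expected counts
  are exactly `control weight × 2^fc`, with a background remainder
  absorbing the difference so expectations sum *exactly* to each library
  size before the multinomial draw,
* contaminant mass fractions of roughly 6.5% rRNA, 1% tRNA and trace
  sn/snoRNA (redundant reads), matching the categorization table the
  worked example reproduces,
* read lengths dominated by 21 and 24 nt, a 21-nt 3' adapter, truncation
  to a fixed 36-nt machine read, per-base substitution errors at 10⁻³
  written at Phred 10,
* a shifted-Zipf background (`w ∝ (rank + 20)^−1.5`) so most background
  uniques stay below the 3-read candidate threshold, as in real
  libraries, without any single sequence dominating a library,
* degradome tags 80% at planted cleavage positions and 20% uniform noise,
* a literature corpus whose first gene family is a hub co-mentioned with
  every other family, with citation frequency decaying by family index,
  and a configurable fraction of non-plant documents.

Reads are sense-strand only (nothing downstream uses strand-specific
logic, and single-stranded truth bookkeeping stays exact). Per-library
seeds derive from the config seed as +0/+1/+2, so libraries are
independent but jointly reproducible; identical configs yield
byte-identical FASTA/FASTQ/TSV output.

What the generator does *not* emulate — and hence what green tests do not
show about real data: indel sequencing errors and quality decay along the
read, polyploid subgenome structure, multi-locus miRNA families with
divergent precursors, expression dispersion beyond multinomial sampling
(no biological replicates, matching the original single-library design),
imperfect hairpins unless `stem_mismatches` is raised, and gene-mention
noise in the corpus (mentions are exact ids, not free text).

## Numerical and degenerate-input conventions

All coordinates are 1-based inclusive. Determinism is enforced at every
tie: lexicographic sequence order in top-N sets, catalog-id order in
assignment ties, center-proximal pairing in the fold, smallest-member ids
for clusters, (contig, start) order for dedupe survivors. Degenerate
inputs have defined behavior rather than errors where a value makes
sense: empty libraries collapse to empty tables, zero-count features are
not-testable rather than infinite fold changes, transcripts without tags
give p = 1, an empty corpus gives an empty rank. The χ² statistic is
computed in double precision (counts × totals overflow 32-bit integers).
Problem sizes in the test suite (15 000-read libraries, 200-miRNA null
calibrations, 1 000-site degradome nulls) were chosen so the full suite
runs in about a minute while keeping Monte-Carlo bands tight enough to
detect real miscalibration.

## Known limitations

* Base-pair maximization is not a free-energy model; it over-pairs random
  sequence, which the stem-segment logic compensates for but cannot
  eliminate. Loci from low-complexity regions deserve skepticism.
* The conserved/novel split depends entirely on the supplied catalog; an
  incomplete catalog inflates "novel" calls.
* χ² on single libraries measures sampling significance, not biological
  reproducibility.
* The binomial degradome null assumes uniform background degradation;
  real degradomes have 5'-bias and hot spots, so real-data p-values are
  anti-conservative.
* CitationRank ranks literature attention, which is not mechanism; the
  hub-recovery guarantee holds for the synthetic corpus design, not for
  arbitrary real corpora.
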