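---
title: "Methods: lncRNA ortholog search and binding-site evolution analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA ortholog search and binding-site evolution analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chirpevo)
```

This vignette documents the models, parameter choices and numerical
conventions behind `chirpevo`. Everything stated here is either a design
decision or a property exercised by the package's test suite; no empirical
claim is made that the tests and `scripts/acceptance.R` do not themselves
compute.

## Coordinates and data model

All internal coordinates are 0-based, half-open `[start, end)`. BED-style
input is native; GFF-style annotation (1-based inclusive) is converted on
read. A single convention end to end removes the usual off-by-one traps
between peak, window and liftover arithmetic. Peak summits are stored as
absolute genomic positions. Reverse-strand liftover follows
`target_offset = tgt_end - 1 - (pos - src_start)`; liftover dialects differ
on this point, so the convention is asserted in tests by round-tripping
through the inverse map. `N` bases are legal in genomes; motif windows
containing `N` are unscorable and skipped.

## The nested-homology ortholog search

The search per query species is: locate anchor proteins → define the
synteny window → scan for motif clusters → confirm a stem-loop → accept
and refine.

**Anchor location.** A full tBLASTn is out of proportion for this
package's scope, so anchors are found by six-frame translation, exact
length-*k* amino-acid seeding (*k* = 5) and ungapped extension under
BLOSUM62, reporting the maximal-scoring locus above
`anchor_min_score = 50` (≈ ten conserved residues beyond the seed). Users
with real genomes can bypass this entirely and supply anchor coordinates.
With two anchors on one scaffold the synteny window is the inter-anchor
interval; a single anchor opens `max_span/2` to each side; anchors on
different scaffolds flag a syntenic disruption. Anchor sets are ordered:
if the primary flanking pair yields no window the search falls back to the
secondary pair, mirroring the situation where a lineage-specific neighbor
replaces the expected one.

**Motif scanning.** Log-odds scores are in bits,
`log2(((count + pc) / colsum) / background)`. Scores are rescaled to
integers at 1/100 bit before a column-by-column convolution builds the
exact null score distribution, from which p-values are upper-tail sums.
The reported window score is the rescaled one, so the p-value is exact for
the score actually reported; the rescaling error is bounded by
`width × 0.005` bits. Granularity of 1/100 bit keeps the DP table a few
thousand entries wide for any realistic PWM. Both strands are scanned and
the hit set is invariant under reverse complementation (tested).

**Cluster election.** The densest window of `cluster_span = 500` bp with
at least `min_hits = 3` hits wins; ties break by more hits, then higher
summed score, then leftmost. The 500-bp/3-hit defaults reflect the
repeated-motif architecture the search targets (clusters of three to six
incidences in one domain). The hit p-value threshold is `1e-4`; the
source analyses did not quantify "high-scoring", so this is our choice,
exposed in `search_params()`. At this threshold an intact consensus of an
8-wide motif passes (p ≈ 1.5e-5) while single-mismatch copies generally do
not, which is what makes the decoy false-positive rate effectively zero.

**Stem-loop confirmation.** Hairpins are scored by exhaustive
maximization over ungapped arm placements: Watson–Crick plus G·T wobble
pairs (the stems are RNA structures read from DNA), arm ≤ 20, loop in
[3, 50], score = paired bases − 1 per internal mismatch (a mismatch
strictly between the outermost and innermost paired positions). Structure
was arguably only visual confirmation in the original workflow; we make it
an explicit filter with `stem_threshold = 6` and allow 0 to disable it.
Tie-breaks are deterministic (first optimum in arm-length, loop-length,
start order).

**Bootstrapping.** Species are processed in increasing patristic distance
from the reference (ties alphabetical, via `ape`'s cophenetic distances).
On acceptance, the hit sequences are appended to the accepted-instance
set, counts are re-tabulated, and the background is re-estimated from the
composition of all synteny windows searched so far. PWM width is constant
across refinement; width mismatches error naming the offending instance.
Rejections carry a reason: `no_assembly_window`, `syntenic_disruption`,
`no_motif_cluster`, or `no_stem`.

## Sequence identity and the homology floor

`pairwise_identity()` is a global Needleman–Wunsch alignment with linear
gap scoring (match +1, mismatch −1, gap −2) implemented in C++ via Rcpp.
Identity is matches per alignment column (end gaps count as columns).
Because the score optimum is usually degenerate, the DP tracks the
lexicographic optimum (score, then matches, then fewest columns), making
the reported identity deterministic; tests verify it against an
independently coded DP and, for the score, against
`Biostrings::pairwiseAlignment`. The homology floor is the mean identity
between each ortholog and `n_scrambles = 2` uniform permutations of the
reference. With gapped alignment the floor for random DNA sits near 50%
(an optimal aligner recruits gaps to manufacture matches); the gapless
variant recovers the theoretical 25% for uniform composition, and both
rise with composition skew. Multiple alignment is deliberately not
reproduced, so cell-by-cell agreement with MSA-derived identity matrices
is out of scope; the floor-versus-theoretical-25% contrast is the target.
Displayed matrices clip to `[floor, 100]`; raw values are retained.

## ChIRP enrichment and Müller-element assignment

Window enrichment is `sum(chirp)/sum(input)` per 1-kb window (the bin size
of the tracks must divide the window). Windows around the lncRNA loci
should be excluded by the caller (antisense probes can recover genomic
DNA directly); zero-input windows are flagged, never divided — this keeps
spurious infinities out of the top bins. Enrichment is linear in the
ChIRP track, which the tests assert.

A scaffold's similarity score for element *E* is its chain score to *E*
divided by its total chain score; the argmax is assigned at
`cutoff = 0.85`. Ties and sub-cutoff maxima are left unassigned and all
per-element scores are reported, replacing a manual-inspection step with a
machine-readable review table. Assignment is invariant to row scaling.

Peak filtering is boundary-inclusive (`q_score ≥ 3000`, `enrichment ≥ 20`
by default), whereas the "strong" subset used in spacing analyses is
strictly exclusive (`> 50`, `> 10000`); both conventions are mirrored
exactly from their definitions and tested at the boundary. `q_score` is
−log10 of the q-value throughout.

## Conservation and turnover

Gene association uses the summit-to-span distance with `max_distance =
1000`; genes lacking annotated UTRs are extended 200 bp upstream and
500 bp downstream in gene orientation first. A peak is gene-conserved
with respect to another species if *any* associated gene has an ortholog
associated with *any* peak there (the existential reading); genes missing
from the orthology table never support conservation. Shared-gene counts
are reported per species subset; when a peak associates with several
genes we count genes, not peaks, in the shared sets.

Element-level turnover lifts the summit (not the whole interval; an
interval mode exists but is off by default), reports 0 inside a target
peak and otherwise the distance to the nearest peak edge; unmappable
summits are excluded from both observed and null curves rather than
counted as infinite. The permutation null relocates target peaks
uniformly within their chromosome (or genome-wide, scaffolds weighted by
length), preserving the length multiset and forbidding overlap. Placement
uses the exact gap construction (uniform points in the free space plus
cumulative lengths), so it needs no rejection sampling and is uniform over
non-overlapping configurations. The null matches the closed form
`P(distance ≤ d) ≈ (2d + len)/L` for a single peak within three standard
errors at 2000 permutations (tested).

## Polypyrimidine tracts and orientation bias

The default tract scorer enumerates substrings with length ≥ 9, C/T
fraction ≥ 0.85 and at most one purine per 10 nt, scoring
`#pyrimidines − 2 × #purines`; it is a pluggable function, so externally
computed tract tables (e.g. from an SVM-based tool) can be injected. The
selection penalty is 0 for distances below 40 bp from the 3′ splice site
and `0.02 × (distance − 40)` beyond — whether base 40 itself incurs 0 or
0.02 is ambiguous in the source description; we chose the penalty-free
reading at exactly 40 and expose both the free zone and the slope.
Ties prefer the candidate closest to the 3′ splice site, then the longest.

Signed peak-to-tract distance is `summit − nearest tract midpoint`,
positive when the summit lies 3′ of the tract in the host gene's
orientation; the within-100-bp fraction uses the absolute distance to the
midpoint (the source endpoint convention is unstated). The permutation
control relocates summits uniformly within their chromosome, and the two
signed-distance distributions are compared by a two-tailed two-sample KS
test. Our KS implementation computes the exact conditional p by lattice
path counting when `m·n ≤ 10000` and the asymptotic Kolmogorov p (with
effective n = mn/(m+n)) otherwise: at tiny samples the asymptotic formula
is off by far more than 10% from the permutation answer, so exactness is
the only way to honor the stated calibration; both regimes are
cross-checked against `stats::ks.test`.

Orientation bias takes the best motif hit per peak (max log-odds over both
strands, ties to forward) and orients it against the host gene's
transcription direction; intergenic summits use the genomic strand. Per
feature class the +/− counts are tested with the two-sided binomial test
by tail doubling, `min(1, 2·min(P(X≤k), P(X≥k)))`, capped at 1. Summits
are classified against all overlapping transcripts (double counting
allowed); fold enrichment divides the class's share of assignments by the
class's share of the genome (transcript-union per class, intergenic = rest).

## Spacing

Nearest-neighbor distances are computed per summit; the perfect spacing
distance is D\* = L/n. The null draws n uniform summits per permutation —
positions, not intervals, hence no minimum-gap constraint. Departure is
summarized on a shared histogram grid (default bin width D\*/10, exposed
since the source binning is unstated): the evenness summary is the
observed-minus-null mass within ±25% of D\*, the clustering summary the
same below 0.1·D\*. On generated regimes (even/random/clustered, 72 peaks
per 1-Mb chromosome), evenness ranks even > random > clustered in at
least 19 of 20 seeds (tested).

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the acceptance suite runs under. Eight species sit on a
caterpillar phylogeny; each genome has an X-like scaffold (element A,
150 kb), two autosomal scaffolds (B, E) and one deliberately ambiguous
scaffold left unassignable (chain scores 0.4/0.3/0.3). The reference X
carries two primary and two secondary anchor genes (60-aa random
proteins, codon-encoded) flanking a planted lncRNA locus: five motif
instances, each the 5′ arm of a hairpin with a 2-nt arm extension and
6-nt loop, separated by 40–70-bp spacers — so each planted instance also
yields an inverted motif copy on the minus strand, exactly as repeated
stem-loop architecture implies. Thirty intron-bearing genes (UTRs
annotated, 500-bp introns ending in a planted pyrimidine tract of length
12–18, pyrimidine fraction 0.95, ending 8–30 bp before the 3′ splice
site) sit on the X and ten on chr2L.

Divergence is substitution-only: per-base rates scale with patristic
distance from the reference (background 0.25 per unit scaled distance,
halved inside genes), hairpin units and tracts mutate at 0.03 (structure
and splicing are conserved features), and anchor coding sequence drifts
only through synonymous codon swaps at 0.30 per codon per unit — the
translated anchor search must stay solvable at high divergence, which is
also the biologically sensible regime. There are no indels, which is what
makes the coordinate maps exact whole-scaffold blocks; one scaffold of
the most distant species is inverted to exercise strand-aware liftover.
Real genomes of course diverge by indels and rearrangement too, so
passing recovery tests here demonstrates correctness of the machinery,
not robustness to assembly noise.

ChIRP experiments plant 50 X peaks and 3 autosomal peaks: input tracks are
flat Poisson (mean 10 per 10-bp bin), ChIRP adds a triangular bump per
peak calibrated so the 1-kb windowed enrichment matches the planned
20-fold; a second RNA track scales the bump by `rox1_ratio = 0.125`,
emulating one dominant RNA. Twenty percent of X summits are placed 15–60
bp from a selected tract midpoint; the remaining summits are kept at
least 120 bp away from tract midpoints so the realized proximal fraction
equals the plan up to rounding (otherwise chance proximity would inflate
it). Every peak receives a motif instance written into the genome at the
summit, oriented relative to the host gene with per-class bias (reverse
0.8 in introns, forward 0.8 in 3′ UTR-like exons by default); a
`class_quota` mode places controlled numbers of intronic and exonic peaks
for calibrated orientation tests. A `conserved_frac` (default 0.4) of X
summits is drawn once and shared by every species at identical
coordinates — these are the planted conserved sites that drive the
gene-level and element-level conservation truths. One global seed fixes
everything; submodules derive child seeds by labeled hashing, so outputs
are byte-identical across runs.

The generator does not emulate: read-level noise (tracks, not FASTQ),
indel evolution, transposable elements, overlapping genes, or
heterogeneous peak widths. The noise model (flat Poisson + triangular
bumps) is the simplest one under which windowed enrichment, summits and
signal bias are all meaningful; all of its knobs are config-exposed.

## Problem sizes and determinism

The test suite runs a reduced simulation (four species, 60-kb X) for
module tests and the full default (eight species, 150-kb X) plus a
400-kb class-quota configuration (100 intronic and 100 exonic peaks) for
the acceptance suite; these sizes keep the whole suite in the
few-minutes range on one CPU while leaving every statistic comfortably
powered. Permutation counts are 100–2000 depending on the precision the
corresponding check needs. Every stochastic stage takes an explicit seed;
nothing reads global RNG state that the caller has not set.

## Known limitations

* The anchor search is ungapped and desk-scale; it is not a BLAST
  replacement for real assemblies.
* Identity values are pairwise-NW-based and not comparable cell-by-cell
  with MSA-derived matrices; only the floor contrast is.
* `map_point` is a per-point loop over blocks — fine for peak-scale data,
  not for base-pair-scale genome-wide lifting.
* The KS exact path assumes no ties; distances from continuous placement
  make ties measure-zero in practice, but heavily discretized input would
  shift the exact p.
* One-to-many orthology is handled existentially; paralog-aware
  conservation calling is out of scope.
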