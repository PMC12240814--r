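---
title: "Somatic structural variants and copy number from long reads: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic structural variants and copy number from long reads: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

svelt detects somatic structural variants (SVs) and somatic copy-number
aberrations from long-read tumor alignments, with or without a matched
normal, and estimates tumor purity and ploidy. This vignette is the package's
account of the underlying models, the tunable parameters and their defaults,
the numerical choices made where several were defensible, and what the
synthetic data used by the test suite does and does not establish about real
data.

## Breakpoint discovery

Long reads supply three kinds of SV evidence. A read whose alignment is split
into a primary and one or more supplementary pieces (the `SA` tag) witnesses
a novel adjacency at each junction between query-adjacent pieces. A read
aligned in one piece can still witness a deletion or insertion as a CIGAR
`D`/`I` operation longer than the minimum SV length (30 bp by default;
events must be strictly longer). Finally, a terminal soft-clip longer than
1,000 bp with no supplementary alignment accounting for those bases indicates
an adjacency whose far side could not be mapped — a single breakend (SBND).

Alignments enter discovery when their mapping quality passes the sample's
gate: MAPQ >= 5 for the tumor, relaxed by a factor 0.5 for the matched
normal (so the effective normal threshold is the real number 2.5 — no
rounding) so that weak germline evidence is still collected and can veto
somatic calls. Similarly, the minimum SV length for CIGAR events is reduced
by a fraction 0.20 in the normal, catching germline indels just below the
tumor cutoff. Unmapped, secondary and duplicate-flagged records are excluded;
duplicate exclusion is a deliberate choice (duplicates would double-count
evidence from one molecule).

Breakend orientations follow the Pan-Cancer notation: `+` means the retained
sequence lies to the left of the breakend. The four strand pairings of
query-adjacent segments map to `(+ -)` deletion-like, `(- +)`
duplication-like and `(+ +)`/`(- -)` inversion-like junctions. CIGAR
deletions are typed `(+ -)` so that gapped and split evidence for one
deletion co-cluster. Adjacent CIGAR deletions separated by mapped stretches
shorter than 30 bp are merged; the reported `sv_length` is the sum of
deleted bases (the biologically meaningful quantity), while the merged
reference span is retained separately — the two differ by the retained
matched bases.

Nanopore data contain a recurrent artifact in which a read aligns forward and
then immediately backward over the same locus, mimicking an inversion
junction. A junction between opposite-strand segments on one contig whose
reference ends lie within 200 bp of each other is suppressed as a
fold-back-like artifact. True inversions, whose junction ends are farther
apart, are unaffected; the test suite verifies both directions (100%
suppression of injected artifacts, 0% suppression of injected inversions
with ends well beyond the window).

A per-haplotype coverage track (5 bp bins; one counter vector per contig and
haplotype, `HP` 1/2/unphased) is built from all primary and supplementary
records and later supplies breakend-level depths. Reads are processed in
non-overlapping genome bins (100 Mb by default) keyed by the primary
alignment's start, so a read is owned by exactly one bin and the result is
identical for any bin size — a property test asserts byte-identical output
at 50 kb versus 100 Mb bins.

## Clustering

Putative breakpoints are grouped per notation class by single-linkage
chaining: a sorted breakpoint joins the current cluster while its distance to
the previous member is at most the window — 10 bp for all classes except
insertions, which use 250 bp because their mapping location is noisier.
Chaining is linear-time and, for points on a line, provably equal to the
connected components of the "within window" graph; the acceptance suite
checks this equivalence against a brute-force component search on 1,000
random instances. Chained groups are then partitioned by mate contig and
re-chained on the mate position with a wider 50 bp window, and insertion
groups are split when consecutive insert sizes differ by more than 25% of
the smaller size (the relative tolerance is this package's concretization of
"comparable size"; no threshold is standard). Cluster positions are member
medians with a lower-median tie-break, which is deterministic and robust to
outlier alignments.

Single-breakend clusters co-located (within the 10 bp window) with any
non-SBND cluster are dropped: longer reads at that locus already resolved
the full adjacency, and the SBND reads are just its truncated observations.

## Classification and conformal confidence

Each cluster is encoded as a frozen, ordered vector of 70 covariates
(`sv_feature_names()`): supporting-read MAPQ statistics; mean/SD/median SV
length; SD and MAD of start and end coordinates; support counts per sample
and per haplotype; allele fractions (support over breakend depth); depth one
coverage bin before, at and after each breakend in tumor and normal; counts
of unphased support and phase sets; the count of normal reads with any
putative breakpoint of any type within 100 bp of either breakend; evidence-
type fractions; notation one-hot; and locus descriptors. Feature identity and
order are part of the model contract: a serialized model refuses a
mismatching table. When no normal is supplied, all normal-derived features
are zero and a `paired_mode` flag feature is off.

Training labels come from matching clusters against an orthogonal
(short-read) call set within 100 bp: matched clusters are somatic, unmatched
ones noise — except that unmatched clusters that look like true somatic SVs
short reads simply missed (at least 6 tumor reads, allele fraction above
0.10, mean MAPQ of at least 50, coordinate SD below 15 for SVs over 100 bp
or below 1.5 with size SD below 10 for shorter ones, and in paired mode
fewer than 2 clustered normal reads with at least 5x normal depth) are
excluded from training rather than mislabeled.

The classifier is a probability random forest (500 trees, maximum depth 20,
fixed seed; 4:1 train/held-out split). The class probability is the fraction
of trees voting somatic, with ties (exactly 0.5) breaking toward noise —
conservative calling. Predicted noise sets the VCF `FILTER` to
`LIKELY_NOISE`; predicted somatic calls are then vetted in a fixed
precedence: fewer than 3 tumor reads gives `LOW_SUPPORT`, allele fraction
below 0.01 gives `LOW_AF`, otherwise `PASS`.

Mondrian conformal prediction supplies per-call confidence with a per-class
validity guarantee. The labeled data are split once (70% trains a forest,
30% calibrates); the nonconformity of an instance for class *c* is one minus
the fraction of trees voting *c*, kept in per-class calibration lists. For a
query, `p_c = (#{calibration scores of class c >= query score} + 1) /
(n_c + 1)`, and the region at tolerance epsilon is the set of classes with
`p > epsilon`: both classes give `both` (an ambiguous instance), neither
gives `null` (an outlier relative to training data). Under exchangeability
the per-class error rate is at most epsilon; the acceptance suite measures
this on synthetic exchangeable data at epsilon in {0.01, 0.05, 0.1}. The
default epsilon is 0.05 (no standard value exists; 0.05 matches the
package-wide significance conventions).

Because shipping a cohort-trained model is impossible here, the package
ships the training *procedure* plus `fit_default_model()`, which trains on a
seeded synthetic corpus of somatic SVs, germline SVs (planted in both
samples, with deliberately unbalanced tumor/normal support so the forest
learns that even weak normal evidence indicates a non-somatic event) and
clustered sub-/near-threshold indel noise at microsatellite-like loci.

## Copy number

The genome is tiled in 10 kb bins, split at PASS breakend positions so
segment boundaries can coincide with SV breakends. Bins with more than 5%
blacklist overlap or more than 75% reference N bases are excluded. (The
N-base rule is stated ambiguously in common usage; exclusion of
predominantly-N bins is the only reading that keeps ordinary genome
analyzable.) Primary reads with MAPQ >= 5 are counted into the bin
containing their alignment start. Paired mode normalizes by the matched
normal with a depth correction, `log2R = log2((t/n) * (sum n / sum t))`;
tumor-only mode self-normalizes by the median retained count. Zero-count
bins are removed rather than producing infinities.

Isolated single-bin spikes are smoothed before segmentation: a point is
replaced by the median of its two-bin neighborhood when it deviates from
that median by more than twice the series MAD and both immediate neighbors
lie strictly on the same side — runs of two or more deviating bins are left
alone, since they may be a real short segment. The series is then
variance-stabilized with the Anscombe transform applied on the ratio scale,
`A(r) = 2 * sqrt(2^log2R + 3/8)`; the log scale can be negative where the
transform is undefined, which forces this choice. Segment means are reported
back on the log2R scale as the mean of member bins.

Segmentation is circular binary segmentation: the arc of the (circularized)
segment maximizing a two-sample t-like statistic against its complement is
accepted as a split when its permutation p-value over 1,000 within-segment
shuffles is below 0.05, recursively; retained changepoints are then
re-validated against their flanking segments at 0.01 with a two-sample
permutation test, dropping the worst failure one at a time (dropping a
changepoint widens its neighbors' flanks, so simultaneous dropping can
discard a true boundary whose flank was artificially short). The statistic's
denominator uses the whole segment's variance, which is permutation-
invariant. Permutations are seeded per segment from the run seed, making
segmentation deterministic given (series, seed). The inner scan is O(n^2)
per permutation and implemented in C++, as segmentation packages in this
field do. Over-segmentation is handled by merging: the threshold is the 20th
percentile (linear interpolation) of |mean log2R difference| over all
segment pairs genome-wide, and adjacent same-contig segments strictly below
it merge iteratively to a fixed point. Exact ties (difference 0) always
merge — with a strict inequality alone, a genome of identical segments would
never merge; with a non-strict one, a two-segment genome would always merge.

## Purity and ploidy

At a heterozygous SNP inside a region of loss of heterozygosity, the BAF of
a pure tumor is 0 or 1; normal contamination pulls both modes toward 0.5 by
(1 - purity)/2 for copy-neutral LOH. The genome is scanned in fixed blocks
(1.2 Mb by default, the median phased-block length in long-read germline
data; toy fixtures use 100 kb, and the block size is a user parameter).
Blocks need at least 10 heterozygous SNPs; blocks with mean depth above
twice the genome mean are excluded as potentially amplified. Remaining
blocks are ranked by the bimodality coefficient of their BAF distribution —
the skewness/kurtosis (SAS) form, `b = (g1^2 + 1) / (g2 + 3(n-1)^2 /
((n-2)(n-3)))`, chosen because it is the standard named form — and the top
10 give purity as the average of `((1 - 2(1 - medBAF_A)) + (1 - 2 medBAF_B))
/ 2` with modes split at BAF 0.5. Fewer than 10 eligible blocks average over
what exists, with a warning. The estimator is exact for copy-neutral LOH
(`rho = 1 - 2 BAF_B`); blocks with other LOH states (for example total copy
1 or 3 with minor 0) bias it, which is why the bimodality ranking matters —
copy-neutral LOH has the widest mode separation and ranks first.

Ploidy is fitted by grid search: purity in `estimate +- 0.1` (step 0.01,
clipped to (0, 1]) against ploidy 1.50-5.00 (step 0.01). Each combination
converts segment log2R to absolute copy number, `CN = ploidy + (2^log2R - 1)
* (ploidy + 2/purity - 2)`, and is scored by the segment-size-weighted RMSD
(or MAD) to the nearest integers. Three plausibility gates discard
combinations: genome fraction at copy number zero must be below 0.1, the
genome fraction within 0.25 of an integer must exceed 0.5 (0.25 is this
package's concretization of "close"; both gates are size-weighted for
consistency, since the zero-state gate is naturally a genome fraction), and
the step between the two most frequent states (by genome size) must be below
2 copies.

The fitness surface is exactly degenerate along whole-lattice shifts:
`(purity', ploidy +- 1)` with `2/purity' = 2/purity -+ 1` maps every segment
to the neighboring integer and fits identically. Among accepted grid points
whose fitness lies within a small margin of the minimum (5% plus 0.003,
covering grid quantization of the shifted lattice), the point whose purity
is nearest the BAF-derived estimate is therefore preferred, with remaining
ties breaking to lower ploidy. The BAF estimate is the right anchor because
copy-neutral LOH pins it independently of the read-depth lattice. Below
roughly 30% purity with near-tetraploid genomes the shifted lattice sits
within the purity window and close to the estimate's own noise, and
recovery genuinely degrades — a known limitation of depth+BAF-only fitting
(this method deliberately does not use somatic point-mutation allele
fractions).

Allele-specific copy number inverts the BAF model at the fitted purity:
with `b` the median mirrored BAF of a segment (values above 0.5 folded, so
the result does not depend on phase) and `n_T` the rounded total copy
number, `n_B = (b (rho n_T + 2(1 - rho)) - (1 - rho)) / rho`, rounded and
clamped to `[0, floor(n_T / 2)]`. The full allele-specific fitting procedure
in the literature is more elaborate; this closed-form inversion is the
package's own choice and is exact in the noiseless limit.

Breakpoints that failed classification are rescued when they lie within
50 bp of a somatic copy-number changepoint, have at least 3 tumor reads, no
normal support and fewer than 3 clustered normal reads of any type; rescue
runs once, after segmentation, and rescued records keep `CLASS=somatic` plus
a `RESCUED` flag for auditability.

## Benchmarking utilities

`split_replicates()` assigns each read — all its records together — to one
of two outputs by a seeded fair coin, simulating sequencing replicates with
equal depth. True somatic SVs should appear in both replicates; artifacts in
one. Running one *normal* replicate as the tumor against the other measures
specificity: an ideal caller reports nothing. `match_breakends()` performs
greedy nearest-first one-to-one matching within a 100 bp buffer (insertions
compare only with insertions) and reports precision, recall and F-measure;
one-to-one matching is this package's choice where multiplicity handling is
not standardized. `phasing_consistency()` tests whether an SV's supporting
reads come from a single parental allele: single-allele support is
concordant; otherwise the majority-allele count is tested one-tailed against
a binomial with success probability 0.95 (allowing a small phasing error
rate), p-values are Benjamini-Hochberg corrected, and q <= 0.05 is
discordant, the rest inconclusive. SVs inside LOH must be excluded upstream
(single-allele support there is vacuous). `foldback_rate()` estimates the
artifact rate per sample from reads with exactly one primary and one
supplementary alignment (both MAPQ >= 20) overlapping in opposite
orientations with read start/end reference positions less than 150 bp apart.

## The synthetic data, and what the tests do and do not show

Alignments are synthesized directly as coordinate-level records (CIGAR plus
`SA` tags) rather than by simulating bases and aligning: the tests target
the caller, not the aligner, and stay at desk scale. The generators invert
the package's own models — bin ratios `r = (rho CN + 2(1 - rho)) /
(rho psi + 2(1 - rho))` with lognormal noise, SNP BAF `(rho n_b + (1 - rho))
/ (rho n_T + 2(1 - rho))` with binomial sampling at roughly 30x and the B
allele on a random parent per site — so parameter-recovery experiments are
genuine generative inversions.

The worked example is a deterministic two-contig (800 kb + 600 kb) tumor-
normal pair: 12 somatic SVs covering every notation class at allele
fractions 0.3-1.0 and 30x depth (supporting-read counts are planted
deterministically as `round(af * depth)`, making the fixture unambiguous),
two germline deletions, and a copy-number layer at purity 0.6 with
size-weighted mean ploidy exactly 2.0, including ten 100 kb copy-neutral
LOH blocks and low bin noise (log2R SD 0.05) so the demonstration fixture is
fully identifiable. The recovery cohort is harder: 20 genomes crossing
purity {0.3, 0.45, 0.6, 0.75, 0.9} with ploidy targets {1.8, 2.0, 3.1, 4.0},
log2R noise SD 0.1 and binomial BAF at 30x; its profiles always place the
two most frequent copy states one copy apart (as in real aneuploid genomes —
a profile whose dominant states are two copies apart is rejected by the
method's own step gate, by design) and carry at least 1 Mb of copy-neutral
LOH. CBS experiments use 500-bin three-state profiles at noise SD 0.15 and
200-bin null series; conformal validity uses 5,000-point exchangeable
feature sets over repeated splits. These sizes were chosen so the entire
suite runs in minutes on one core while keeping every statistical check
adequately powered.

What passing these tests shows: the machinery is internally correct — the
notation algebra, the clustering equals its brute-force definition, the
statistics are calibrated, the estimators invert their own generative
models, artifacts constructed to the artifact definition are removed. What
it does not show: performance on real long-read data, where alignment error
is not independent across reads, microsatellite noise is far more
structured, mapping quality is locus-dependent, and the classifier must be
trained on real matched short-read labels rather than the synthetic corpus.
The shipped default model is a stand-in for tests and demonstrations, not a
trained release model.

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates every fixture
from the seed, runs the full pipeline and the statistical experiments, and
writes the headline quantities (recall/precision on the worked example,
replicate concordance, normal-vs-normal false positives, purity/ploidy
recovery, CBS recovery and type-I rates, conformal error rates, fold-back
suppression and rate recovery, clustering-oracle agreement) as JSON. The
test suite (`testthat::test_dir("tests/testthat")`) covers the same ground
with assertions at the tolerances stated above.
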