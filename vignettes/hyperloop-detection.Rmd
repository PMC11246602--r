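---
title: "Detecting hyperloops: model, assumptions and design choices"
author: "hyperloopR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hyperloops: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperloopR)
```

## The problem

Proximity-capture technologies such as SPRITE (split-pool barcoding) and
Pore-C (nanopore sequencing of ligated concatemers) report *multi-way*
chromatin contacts: each sequencing cluster is a set of genomic fragments
that were captured together in one molecular complex. Two confounds make
raw co-occurrence uninformative about regulatory structure. First, the
random polymer looping effect: contact probability decays with genomic
distance, so nearby loci co-occur constantly for purely physical reasons.
Second, multiplicative technical biases (GC content, mappability, fragment
density) modulate how often each genomic bin is observed at all.

hyperloopR detects **hyperloops**: multi-way bin sets whose observed
frequency is significantly higher than expected under random polymer
looping with technical biases, and whose bins are connected by significant
pairwise chromatin loops.

## The detection pipeline

Clusters are binned at a fixed resolution and processed per chromosome:

1. Every cluster of $k$ bins is decomposed into its $\binom{k}{2}$
   unordered bin pairs, accumulating a Hi-C-like sparse contact matrix
   $M$.
2. Per-bin multiplicative biases $b_i$ (mean 1 over usable bins) are
   estimated by iterative matrix balancing of $M$, solving
   $M_{ij} = B_i B_j M^*_{ij}$ under an equal-visibility constraint that
   excludes the diagonal and adjacent bins ($|i-j| \le 1$).
3. Significant pairwise loops are called with a distance-decay binomial
   test (below), or imported from a BEDPE file produced by an external
   caller.
4. All bin sets of size $k_{\min}..k_{\max}$ whose support (number of
   containing clusters) reaches `minSupport` are enumerated with an
   FP-growth miner; candidates whose bins are not *connected* by loop
   edges are discarded.
5. Each surviving candidate receives an expected frequency and a binomial
   p-value under the background model, followed by Benjamini-Hochberg
   correction stratified by (chromosome, size).

Connectivity rather than clique-ness is required in step 4: spatial
co-location is transitive, so a connected set of loci implies the full
clique of spatial contacts, while demanding every pair to be an
individually significant loop would be needlessly stringent.

## The background model

For a candidate with sorted bins $x_1 < x_2 < \dots < x_k$ and gaps
$d_j = x_{j+1} - x_j$, the per-experiment sampling probability is

$$ p = \frac{1}{n} \prod_{j=1}^{k-1} P_k(d_j), $$

where $n$ is the number of bins on the chromosome and $P_k$ is a
size-specific gap-distance distribution. The product over *adjacent* gaps
is a maximum-spanning-tree approximation: among all connected graphs on
the candidate's bins, the path through consecutive loci maximizes the
product of power-law-decaying edge probabilities, so it is the dominant
way a random chain of pairwise loops produces the candidate.

$P_k$ is learned from the data being tested by a two-step decomposition:
every cluster of size $s$ is notionally decomposed into its
$\binom{s}{k}$ size-$k$ subsets, and every subset into its
$\binom{k}{2}$ pairs. Because each pair of a cluster lies in exactly
$\binom{s-2}{k-2}$ of the $k$-subsets, this is implemented as a weighted
pair-distance histogram with weight $\binom{s-2}{k-2}$ -- no subset
enumeration is ever materialized. The trial count is
$N_k = \sum_i \binom{|c_i|}{k}$, the number of size-$k$ draws the observed
cluster collection represents. The expected frequency is
$\lambda = p N_k$, corrected for technical biases as
$p^* = p\, b_{x_1} \cdots b_{x_k}$ and $\lambda^* = p^* N_k$, and the
p-value is the upper binomial tail $P(K \ge \mathrm{observed})$ with
$N_k$ trials and success probability $p^*$, evaluated through the
regularized incomplete beta function (`pbinom`), which is stable for the
$N_k \sim 10^5$-$10^7$ regime.

### Multiple testing

Benjamini-Hochberg correction is applied independently within each
(chromosome, size-$k$) family. Candidate families of different sizes have
radically different counts and null behaviour; pooling them would let the
enormous 3-way family dominate the ranking of 4- and 5-way candidates.
Finer stratifications (e.g. by distance stratum) are possible but are not
implemented; size stratification is the simplest defensible grouping.

## Pairwise loop calling

The built-in caller is deliberately simple (external loop sets can always
be supplied via BEDPE). Bias-normalized counts $M_{ij}/(b_i b_j)$ at
distances $d \ge 2$ are pooled into `nBands` equal-occupancy distance
bands; the per-band contact probability is the band's share of normalized
contacts divided by its number of possible pairs, and a weighted
pool-adjacent-violators fit enforces the monotone non-increasing decay
expected of random polymer looping (isotonic smoothing replaces the
spline refinement of full Fit-Hi-C-style callers). Each stored pair is
then tested against the binomial with success probability
$P(d)\, b_i b_j$ and the total in-range contact count as trials, with BH
correction over all tested pairs of the chromosome.

## Technical biases and matrix balancing

`iceBiases()` implements two schemes:

* **Plain** (default of the function): alternating marginal scaling of the
  restricted matrix until all valid bins have equal marginals. This is
  classic iterative correction and solves the stated equal-visibility
  equations exactly.
* **Decay-normalized** (`decayAware = TRUE`, the pipeline default): each
  iteration re-estimates the mean normalized count $f(d)$ per distance and
  compares every bin's marginal against its *expected* marginal
  $\sum_j f(|i-j|)$ over available partner bins.

The second scheme exists because equal marginals are the wrong target
near chromosome ends: a terminal bin is missing its close -- and therefore
contact-rich -- partners on one side, so its marginal is genuinely smaller
even when it carries no technical bias. Plain balancing folds this
geometry into $b_i$, which then mis-corrects both the loop caller's
expectations and $\lambda^*$ in the candidate test (underestimating the
expected frequency of short-range contacts near the ends and producing
spurious candidates there). Normalizing by the decay-expected marginal
isolates the factorizable technical component. On synthetic data with
known planted biases this is directly measurable as a higher correlation
between estimated and true bias vectors; the test suite asserts it.

Bins with a zero restricted marginal (or below `minMarginalFraction`
times the median) are flagged invalid; candidates touching an invalid
bin are dropped at the connectivity stage because their bias product is
undefined.

## Handling unobserved gap distances

A candidate may have a gap distance never seen in the learned histogram.
Setting $P_k(d) = 0$ would make the candidate either untestable or
spuriously certain, so the default (`interpolation = "interpolate"`)
fills interior gaps by log-linear interpolation between the nearest
observed distances and extrapolates beyond the largest observed distance
with a power-law tail fitted to the upper half of the histogram (slope
capped at zero). The strict `"zero"` mode is retained; in it, candidates
with vanishing probability get `p_value = NA` and are excluded from the
BH family.

## The synthetic data generator

`generateNullClusters()` draws exactly the process the background model
assumes: cluster size from a truncated geometric distribution
(`minSize = 2`, `maxSize = 10`, success probability 0.35, giving a
SPRITE-like median size of 3-4), a uniform start bin, and i.i.d. gaps
from a truncated power law $P(d) \propto d^{-\alpha}$ on $1..d_{\max}$
($\alpha = 1.2$, $d_{\max} = 40$ on a 500-bin chromosome by default --
a Hi-C-like decay exponent with gap support an order of magnitude below
the chromosome length). Clusters whose span does not fit are redrawn.
Technical biases are injected by *thinning*: each bin of each cluster is
retained with probability proportional to its bias (scaled so the
largest bias retains always), which is precisely the observation model
under which a factorizable bias arises. Ground truth (bias vector, gap
distribution, planted tuples) is returned alongside.

Planted positives (`plantHyperloops()`, `randomPlantedTuples()`) append
`extraSupport` clusters consisting of exactly the tuple's bins. The
default planting geometry draws consecutive gaps uniformly on 40-120
bins: planted contacts then sit in the distance regime where random
multi-way co-occurrence is rare, which is what a planted-signal recovery
experiment is meant to probe. Tuples planted inside the short-distance
bulk of the polymer background are a different (and much harder)
detection problem: there the pairwise background at realistic depth
swamps a small support increment before the loop caller can anchor the
tuple.

What the generator does *not* emulate: TADs and compartments (block
structure in the contact matrix), locus-specific loop enrichment in the
null, inter-chromosomal contacts, and the heavy upper tail of SPRITE
cluster sizes. Passing tests therefore demonstrate correctness of the
statistical machinery under the model's own assumptions, not performance
on the full complexity of real nuclear organization.

## Numerical and design choices

* Bins are 0-based half-open intervals; interval inputs (Pore-C monomers)
  are reduced to midpoints before binning; duplicate bins within a
  cluster collapse (a hyperloop is a *set* of bins).
* Inter-chromosomal projections of a cluster are analyzed independently
  per chromosome; single-bin projections are dropped.
* The default cluster-size filter is 2-1000 bins: giant SPRITE clusters
  (nuclear speckles, whole compartments) would blow up both the FP-tree
  and $N_k$ while carrying little locus-specific information.
* FP-growth orders items by descending global support with ties broken by
  ascending bin index, making the output deterministic; results are
  emitted sorted by size then lexicographically. Mining is capped at
  `kMax` (default 5) by pruning the recursion depth.
* The miner is implemented in C++ (Rcpp); everything else is vectorized R
  on sparse triplet structures.
* Start-point probability is $1/n$, ignoring edge truncation of spans;
  this keeps the formula exact for interior candidates and is one reason
  the decay-normalized balancing matters near ends.
* Balancing defaults: `tol = 1e-5`, `maxIter = 200` (the pipeline allows
  500); convergence state is reported on the `BiasVector` rather than
  enforced.
* `gapPairConcordance()` -- the goodness-of-fit diagnostic comparing mean
  observed and expected 3-way frequencies per gap-pair group -- supports
  coarse log-spaced gap binning and a minimum observed-count filter. At
  depths where most exact gap pairs are observed 0-1 times, log-scale
  residuals of near-empty groups measure counting noise rather than model
  fit; the coarse view (12 log-spaced bins per axis, groups with at least
  10 observations) is the appropriate regime for judging bias modeling.
* Problem sizes in the test suite were chosen to exercise the method at
  realistic per-bin coverage while staying desk-scale: 500-bin
  chromosomes with $5 \times 10^4$ clusters for calibration and
  planted-recovery experiments, 300 bins with $10^5$ clusters (deep
  coverage, proportionally scaled $d_{\max} = 24$) for bias recovery,
  and 20-30-bin instances for brute-force oracle comparisons.

## Known limitations

* The adjacent-gap product systematically underestimates expected
  frequencies of candidates whose *non-adjacent* pair distances carry
  most of the co-occurrence mass, and the size-specific distributions are
  learned from all pairs rather than adjacent pairs only; both
  approximations follow the model's design and are visible as residual
  structure in the concordance diagnostic at the shortest and longest
  gaps.
* $P_k$ is learned from the same cluster set being tested; strong true
  signal inflates the background slightly (conservative).
* The built-in loop caller has no local-neighborhood (peak) model; for
  data with strong TAD structure an external caller via BEDPE is
  preferable.
* Shuffle-based empirical FDR preserves per-cluster gap vectors but
  redraws starts uniformly per chromosome; it does not preserve
  large-scale coverage gradients.
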