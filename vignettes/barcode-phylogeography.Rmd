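---
title: "Barcode phylogeography with mitopop: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode phylogeography with mitopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopop)
```

## Scope and data model

`mitopop` analyses a single aligned mitochondrial barcode locus sampled in
many individuals across structured populations. Its universe is an
equal-length DNA alignment plus a sample table mapping each individual to a
population, a country and a higher-level group, optionally with
coordinates. All statistics flow from two derived objects: the *haplotype
set* (distinct sequences with frequencies and member lists) and pairwise
*distance matrices* (p or K2P) over individuals or haplotypes.

Two missing-data conventions coexist deliberately, matching how the
standard desktop tools behave. Haplotype identity and all site statistics
use **complete deletion**: any column containing a gap or ambiguity code in
any record is dropped, so every comparison happens over one fixed site
universe. Distance matrices use **pairwise deletion**: each pair is
compared over the columns where both sequences carry an unambiguous base,
which wastes less information when missing data are scattered. Both site
counts are available from the respective objects, so a user can always
state which universe a number refers to.

## Diversity and neutrality statistics

Haplotype diversity uses the unbiased estimator
$h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$; nucleotide diversity is
the frequency-weighted mean per-site p-distance between haplotypes with the
same $n/(n-1)$ correction, and $\bar k = \pi L$ is the mean number of
pairwise differences. Both are invariant to haplotype relabelling, which
the tests assert.

Tajima's $D$ contrasts $\bar k$ with the segregating-site estimator
$S/a_1$, normalised by the usual $e_1, e_2$ constants. $D$ is reported as
`NA` when $S = 0$ (the statistic is undefined there; degenerate inputs
never silently become zeros in output tables).

Fu's $F_s$ is the log-odds of observing at least the sampled number of
haplotypes under the Ewens sampling distribution with
$\theta = \bar k$ — the mean-pairwise-difference estimator, the natural
plug-in given that no other estimator is implied by the statistic's
construction. The tail probability requires unsigned Stirling numbers of
the first kind $|s(n,k)|$, which overflow doubles long before the sample
sizes barcoding reaches ($n$ in the hundreds); the implementation therefore
carries the whole Stirling row and all products in log space with
log-sum-exp, and the normalising constant cancels between the
$P(K \ge K_{obs})$ and $P(K < K_{obs})$ sums, so $F_s$ is just a difference
of two log-sums. The test suite pins this path against an exact
big-integer evaluation of the same tail for every $n \le 25$: at
$(n, K, \theta) = (686, 64, 1.90)$ the log-space value is $-74.9$, the
magnitude scale reported for large expanding barcode samples. $K_{obs}=1$
makes the tail probability exactly 1 and is returned as `+Inf` rather than
a fake large number.

## Distance-based AMOVA and its permutation schemes

The molecular variance decomposition works directly from a pairwise
distance matrix: the total sum of squared deviations is
$\mathrm{SSD} = \frac{1}{N}\sum_{i<j}\delta^2_{ij}$, with within-population
and within-group terms computed the same way inside each stratum and the
remaining levels obtained by subtraction. Variance components come from the
mean squares through the coefficients $n', n'', n'''$ determined by the
(generally unbalanced) population sizes, and the fixation indices are
$\Phi_{CT} = \sigma^2_a/\sigma^2_T$,
$\Phi_{SC} = \sigma^2_b/(\sigma^2_b + \sigma^2_c)$,
$\Phi_{ST} = (\sigma^2_a + \sigma^2_b)/\sigma^2_T$.

Following the convention of molecular-distance AMOVA, $\delta^2$ **is the
distance itself** (a K2P distance is already a squared-deviation-like
dissimilarity on the evolutionary scale); `square_distances = TRUE` gives
the literal squared alternative. SSD additivity and percentage
normalisation are asserted inside `amova()` on every call, not only in
tests.

Each Φ statistic is tested with the permutation scheme that matches its
null: individuals among all populations for $\Phi_{ST}$, individuals among
populations within their group for $\Phi_{SC}$, and whole populations among
groups for $\Phi_{CT}$. All p-values use $(b+1)/(B+1)$, which is never
exactly zero and keeps the null distribution of p-values uniform (a
property the suite checks with a Kolmogorov–Smirnov test over simulated
null datasets). Pairwise $\Phi_{ST}$ is literally the two-population AMOVA
of each pair — the tests require equality to $10^{-12}$ — and slightly
negative values are preserved as "no detectable differentiation", never
clamped.

## Geography and isolation by distance

Geographic distances are great-circle (haversine) on a sphere of radius
6371.0088 km, with population positions defaulting to the centroid of
member coordinates. A vague "Euclidean distance between central locations"
is not reproducible; the haversine centroid rule is, and it can be
overridden by passing explicit per-population coordinates.

The Mantel statistic is the Pearson correlation over lower-triangle
entries; significance comes from joint row/column permutations of the
second matrix, two-sided on $|r|$, with exact enumeration of all $n!$
permutations when $n \le 7$. Untransformed matrices are the default;
$F_{ST}/(1-F_{ST})$ linearisation and log-distance are available as flags
because web-era IBD tools offered them and published analyses do not always
say which was used. On the packaged region and country fixtures the
untransformed configuration reproduces the published $R^2$ values (0.345
vs 0.355 printed, 0.504 vs 0.505), so it is the recorded configuration.

## The barcode gap criterion

ABGD partitions sequences at a distance threshold found from the ranked
pairwise distances, then recurses within every group of three or more
until nothing splits, scanning log-spaced priors $P$ between `P_min` and
`P_max`. The gap rule used here: walk the *distinct* ranked distances and
accept the first gap $g_i = d_{(i+1)} - d_{(i)}$ whose right edge exceeds
$P$ and which satisfies $g_i > X\,d_{(i)}$ — the gap must be $X$ times
wider than the entire intraspecific divergence below it.

This relative-width criterion is a deliberate design choice. A baseline
built from the local spacing of ranked distances (mean gap of the prefix)
degenerates on barcode data, where distances are quantised to multiples of
$1/L$ with sub-$10^{-6}$ spread induced by the K2P correction: every
mutation-count boundary then looks like a gap and tiny priors shatter true
clades. Requiring the gap to dwarf the intraspecific *maximum* instead
encodes what "barcode gap" means operationally (interspecific divergence
well clear of intraspecific divergence), is invariant to how finely the
intraspecific cloud happens to be sampled, and makes the partition count
provably non-increasing in $P$ (larger priors only remove candidate gaps).
Both properties — monotonicity over random data and recovery of four
planted clades at priors up to 0.008 with the default $X = 1.5$ — are
exercised in the acceptance tests. Groups of fewer than three sequences
are never recursed into, thresholds sit at gap midpoints, and edges use
strict `<`, so ties cannot straddle a boundary.

## Median-joining networks

The network stage connects haplotypes under the weighted Hamming metric
(transversions 3×, optional per-site weights for downweighting
hypervariable positions; weights default to uniform because published
hypervariable-site weightings are rarely specified). Construction follows
the median-joining recipe in three phases:

1. **ε-relaxed minimum spanning network**: an edge $(u,v)$ enters when its
   length is within $\varepsilon$ of the cheapest connection between the
   clusters of $u$ and $v$ — implemented as $d_{uv} \le$ (minimax path
   weight between $u$ and $v$) $+\ \varepsilon$, which contains every MST
   and is edge-monotone in $\varepsilon$ (tested).
2. **Median insertion**: for connected triplets, the site-wise majority
   consensus is a candidate latent haplotype; ties generate all candidate
   states (resolved deterministically by lexicographic order, capped
   combinatorially). The candidate that most reduces the cost of spanning
   the node set is added, and the process iterates to a fixed point, so the
   spanning cost is non-increasing by construction.
3. **Maximum-parsimony pruning**: links that lie on no minimal-cost path
   between two *observed* haplotypes are removed, then median vectors of
   degree ≤ 2 are contracted away, so surviving medians always have degree
   ≥ 3 and observed haplotypes remain connected (asserted).

On exhaustive instances (≤ 5 haplotypes, ≤ 6 variable sites) the resulting
spanning cost equals a brute-force Steiner minimum over the full per-site
state product space; the greedy insertion is a heuristic in general, and on
large networks it inherits the usual caveat that median networks
approximate, not solve, the Steiner problem.

## The synthetic generators and what they do (not) emulate

The **star expansion** model generates, per clade, a founder placed a fixed
number of substitutions from a shared root, and gives each individual an
independent Poisson($\lambda$) load of private mutations at fresh sites.
This is the limiting genealogy of a strong recent expansion: an excess of
singletons around high-frequency founder haplotypes, hence negative
Tajima's $D$ and Fu's $F_s$ (the suite verifies the sign over 200
replicates). Clade divergences create an arbitrarily wide barcode gap, and
two clades with founder distance $\delta$ and load $\lambda$ plant
$\Phi_{ST} = \delta/(\delta + 2\lambda)$ in expectation (within-population
pairs differ at $2\lambda$ sites on average, between-population pairs at
$\delta + 2\lambda$; with the distance-as-$\delta^2$ convention the
components are $\sigma^2_b = \delta/2$ and $\sigma^2_c = \lambda$, up to
the $1/L$ scale that cancels in the ratio). The default acceptance check
plants $\delta = 4, \lambda = 2$ for $\Phi_{ST} = 0.5$ and recovers it
within ±0.05 over 100 replicates.

The **neutral coalescent** draws a Kingman genealogy (exponential waiting
times at rate $\binom{k}{2}$) and drops Poisson($\theta/2 \times$ branch
length) mutations, giving $E[\pi] = \theta$ per sample pair and
$E[S] = \theta a_1$; it calibrates the neutrality tests' null (mean $D$
within ±0.15 and mean $F_s$ within ±0.5 at $n = 30$, $\theta = 5$ over 500
replicates) and the unbiasedness of $\pi$ (relative bias below 5% over 500
replicates at $n = 20$, $\theta = 5$ — replicate counts chosen so each
check runs in seconds while the Monte Carlo error stays a few times below
the tolerance it guards).

Both generators use **infinite sites**: every mutation hits a previously
untouched position (exhaustion is a hard error), so $S$ equals the number
of mutation events exactly and truth records list every placement.
Transversions occur with probability 0.1 per mutation, echoing the
transition-dominated spectra of real insect mitochondrial barcodes.

What the simulations do *not* emulate — and therefore what passing tests
cannot certify about real data — includes recurrent/back mutation at a
site (finite-sites homoplasy), recombination (absent in animal mtDNA but
relevant to other loci), migration between demes, selection, sequencing
error, and missing data patterns. The IO layer handles gaps and ambiguity
codes, but no generator produces them; tests of the deletion conventions
use hand-built fixtures instead.

## Packaged fixtures

Three small TSV fixtures transcribe published summary tables: a 64-row
haplotype frequency spectrum (686 individuals; its pooled haplotype
diversity is 0.801 to three decimals), and joint matrices for 20
country-level populations and 9 continental regions with pairwise
$F_{ST}$ below the diagonal and kilometre distances above. One cell of the
region table is printed with a garbled thousands separator in the source
("16,.049"); it is transcribed as 16049 km, consistent with its
neighbours. The printed kilometre matrices are used as-is rather than
recomputed, because the exact reference points behind them are not stated.

## Numerical conventions

* p-values: $(b+1)/(B+1)$ everywhere; $B$ defaults to 1000; seeds are
  explicit arguments, and simulations are bit-reproducible from
  (configuration, seed).
* Undefined statistics propagate as `NA` (with a warning at the point of
  computation), `+Inf` marks the $K_{obs} = 1$ Fu's $F_s$ boundary, and
  saturated K2P pairs (log argument ≤ 0) are `NA` entries that
  `nj_tree()` refuses to accept silently.
* Negative NJ branch lengths are clamped to zero with a message.
* Haplotype ids are assigned in order of first appearance and frequency
  ties are never reordered, so outputs are stable under re-runs.
* Ranked-distance ties in ABGD are collapsed before gap scanning; group
  numbering follows matrix label order, and the partition itself is
  invariant to input order.
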