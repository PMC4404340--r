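# mitopop

Population-level surveys of a single mitochondrial barcode locus (typically
a *cox1* fragment of ~600 bp sequenced in hundreds of individuals across
many sampling sites) all ask the same chain of questions: how many distinct
haplotypes are there and how are they shared among sites; how diverse is
each population; does the site-frequency spectrum betray demographic
expansion; how is molecular variance partitioned among regions; does genetic
differentiation track geography; do the sequences fall into discrete
clusters separated by a "barcode gap" (candidate species); and what does the
haplotype genealogy look like as a network? `mitopop` implements that entire
chain as composable R functions plus a one-shot pipeline, together with a
synthetic-data generator so every stage can be verified at desk scale
against known truth.

## What it computes

* **Haplotype collapsing** — individuals identical over the analysis sites
  (columns free of gaps and ambiguity codes, i.e. complete deletion) share
  a haplotype; site summaries count segregating sites *S*,
  parsimony-informative sites, and transition/transversion substitutions.
* **Diversity and neutrality** — haplotype diversity
  *h* = *n*(1 − Σ*p*ᵢ²)/(*n* − 1); nucleotide diversity
  π = *n*/(*n* − 1) Σᵢ<ⱼ 2*p*ᵢ*p*ⱼ*d*ᵢⱼ with *k̄* = π·*L*; Tajima's
  *D* = (*k̄* − *S*/*a*₁)/√(*e*₁*S* + *e*₂*S*(*S* − 1)); Fu's
  *F*ₛ = ln(*S*′/(1 − *S*′)) where *S*′ = P(*K* ≥ *K*obs) under the Ewens
  sampling distribution at θ = *k̄*, computed in log space via Stirling
  numbers of the first kind.
* **Distances and trees** — Kimura two-parameter distance
  *d* = −½ ln(1 − 2*P* − *Q*) − ¼ ln(1 − 2*Q*) under pairwise deletion;
  neighbor-joining trees with optional outgroup rooting.
* **Population structure** — distance-based AMOVA (two- and three-level)
  with Φ-statistics (Φ\_ST, Φ\_SC, Φ\_CT), permutation p-values under the
  level-appropriate permutation schemes, pairwise Φ\_ST matrices,
  great-circle distances (haversine, R = 6371.0088 km), and Mantel
  matrix-correlation tests (exact enumeration for ≤ 7 labels).
* **Species delimitation** — Automatic Barcode Gap Discovery: recursive
  partitioning at the first pairwise-distance gap wider than *X* times the
  intraspecific divergence below it, scanned over log-spaced priors *P*.
* **Haplotype networks** — median-joining networks with ε relaxation,
  transversions weighted 3× transitions, consensus median vectors, and
  maximum-parsimony pruning of superfluous nodes and links.
* **Simulators** — a star-expansion model (founder haplotypes plus private
  Poisson mutation loads; the post-expansion genealogy) and a neutral
  Kingman coalescent, both under infinite sites with full truth records.

## Worked example

Two diverged clades (an "Asian" star expansion and an "African" one, 30
founder substitutions apart), 25 individuals each at 600 sites:

```r
library(mitopop)

cfg <- star_config(
  L = 600,
  clades = list(
    list(name = "asia",   divergence = 0,
         populations = list(list(name = "vn", n = 25, lat = 16,   lon = 106))),
    list(name = "africa", divergence = 30,
         populations = list(list(name = "ke", n = 25, lat = -0.5, lon = 37)))),
  lambda = 1, seed = 42)
sim  <- simulate_star_expansion(cfg)
hset <- collapse_haplotypes(sim$aln)
diversity_summary(hset)
#>    n  K         h        pi     kbar  S          D        Fs
#> 1 50 35 0.9477551 0.0285102 17.10612 75 0.07610455 -7.655277

d  <- distance_matrix(sim$aln, model = "k2p")
amova(d, sim$samples$population, B = 999, seed = 1)
#> AMOVA (distance-based)
#>              source df      SSD  variance percent
#>   among_populations  1 0.660645 0.0263655  94.596
#>  within_populations 48 0.072297 0.0015062   5.404
#>               total 49 0.732942 0.0278717 100.000
#>
#> Phi statistics:
#>   Phi_ST  =   0.9460  (p = 0.001)

scan <- abgd_partition(distance_matrix(hset, model = "k2p"))
scan[[1]]$n_groups   # 2 -- the two planted clades
net  <- build_mjn(hset, epsilon = 0, tv_weight = 3)
net
#> median-joining network: 35 haplotypes + 0 median vectors, 34 links; spanning cost 87
annotate_network(net, hset, sim$samples)$founder
#> "H2"   -- the untouched founder haplotype of the larger radiation
```

The two pooled clades give strongly positive Φ\_ST (nearly all variance
between populations), ABGD finds the two planted groups across the default
prior range, and the network's founder node is the modal haplotype at the
centre of its star — the same reading one applies to real barcode surveys.

The package also ships transcriptions of a published 64-haplotype frequency
spectrum (*n* = 686) and joint pairwise-FST / geographic-distance matrices
for 20 populations and 9 regions:

```r
haplotype_diversity(haplotype_frequency_fixture()$frequency)
#> 0.8010725
rm <- region_matrix_fixture()
mantel_test(rm$fst, rm$km, B = 10000, seed = 1, exact = FALSE)
#> Mantel test: r = 0.5875, R2 = 0.3452, p = 0.0064 (permutation, B = 10000)
```

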