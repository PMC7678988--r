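---
title: "Comparing soil microbiomes with their cellulolytic culturomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing soil microbiomes with their cellulolytic culturomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdiv)
```

## The problem

Plating a soil suspension on a selective medium — here, a mineral medium
whose only carbon source is cellulose — recovers a *culturome*: the subset
of the soil community able to grow under those conditions. Comparing 16S
amplicon profiles of bulk soil with profiles of the washed plates asks two
questions at once. First, how much of the community is recovered, and does
a phylotype's success on the plate reflect its abundance in the soil?
Second, when two contrasting soils (a sod-podzolic soil, SP, and a
chernozem, CZ) are compared, at what *phylogenetic depth* do their
communities differ — and is that depth the same for the bulk communities
and for their culturomes?

`cdiv` implements the full analysis pipeline for these questions on a
phylotype (ASV) count table, a rooted phylogeny, and a sample metadata
table with two factors: `soil_type` (SP/CZ) and `fraction`
(bulk/culturome). A synthetic-community generator with the same data
contracts makes every stage testable end to end.

## Normalisation and diversity

Samples are rarefied to the smallest library size by without-replacement
(multivariate hypergeometric) subsampling; with-replacement sampling would
bias richness. All randomised steps take an explicit integer seed. Alpha
diversity reports observed richness, Shannon entropy in nats
($H = -\sum p_i \ln p_i$), Pielou evenness $H / \ln S$, and inverse
Simpson $1/\sum p_i^2$.

Four beta-diversity metrics are available, all returning standard `dist`
objects:

* **Bray-Curtis** $\sum_i |x_i - y_i| / \sum_i (x_i + y_i)$;
* **unweighted UniFrac** — branch length unique to one community's tip
  set over branch length observed in either;
* **weighted UniFrac**, normalised so
  $\sum_k b_k |p_k - q_k| / \sum_k b_k (p_k + q_k) \in [0,1]$, where
  $p_k, q_k$ are subtree relative abundances (a flag exposes the raw
  numerator);
* **between-community MPD** — the mean cophenetic distance over
  cross-community tip pairs, presence-based by default because that is how
  the statistic is conventionally used (a flag enables abundance
  weighting). MPD-between is not a metric: a community against itself
  returns its within-community mean pairwise distance.

## Ordination and group statistics

PCoA is classical scaling of the double-centred $-\tfrac12 D^2$ matrix.
Negative eigenvalues are reported but never used for coordinates, and no
Cailliez or Lingoes correction is applied unless asked for — corrections
change distances, so they should be a deliberate choice.

PERMANOVA partitions the total sum of squared distances
($SS_T = \sum_{i<j} d_{ij}^2 / n$) into between- and within-group parts
and refers the pseudo-F to a permutation distribution. The p-value uses
the add-one correction $p = (\#\{F^\pi \ge F\} + 1)/(B+1)$ with $B = 999$
permutations by default, so it can never be exactly zero; a matrix of
explicit permutations can be supplied instead for exact enumeration on
small designs. A complete-separation design yields $F = \infty$, which is
handled as a legitimate maximal statistic; only a constant distance matrix
(0/0) flags the result as undefined.

The distance between two groups' centroids is computed directly from the
distance matrix through the squared-distance identity
$$\delta^2 = \frac{\sum_{i \in a, j \in b} d_{ij}^2}{n_a n_b}
 - \frac{\sum_{i<i' \in a} d_{ii'}^2}{n_a^2}
 - \frac{\sum_{j<j' \in b} d_{jj'}^2}{n_b^2},$$
which needs no coordinates and is exact for Euclidean-embeddable
distances. For non-Euclidean input $\delta^2$ can be negative; the value
is then reported as 0 with a `non_euclidean` flag rather than silently
truncated.

## The agglomeration ladder and divergence curves

Phylotypes are agglomerated by single linkage on cophenetic (tip-to-tip
path) distances: at threshold $t$ the clusters are the connected
components of the graph joining taxa at distance $\le t$. The closed
threshold makes $t = 0$ well defined when duplicate tips are present.
Cluster ids are the smallest member taxon id, so partitions are fully
deterministic.

The default ladder places 40 levels on evenly spaced quantiles of the
single-linkage *merge heights*, plus threshold 0. Spacing levels on
quantiles of the raw pairwise distances looks natural but fails in
practice: on realistic phylogenies most tip pairs coalesce near the root,
so even the 2.5% distance quantile collapses hundreds of taxa into a few
dozen clusters in a single step and leaves no usable resolution gradient.
Merge-height quantiles guarantee movement at every level and an
approximately linear decay of the cluster count. A `linear` ladder over
the distance range is also provided, as is collapsing by taxonomy rank
(`collapse_by_rank()`) as an alternative notion of "level".

For one fraction, the *divergence curve* records at every ladder level the
percentage of clusters shared between the two soils,
$100\,|SP \cap CZ| / |SP \cup CZ|$. The union denominator is the only
symmetric choice. Presence means at least 1 read in at least 1 sample of
the group, applied to the rarefied table so that detection effort is
equal; both thresholds are adjustable. The curve is summarised by an OLS
regression of the shared percentage on the merged-taxon fraction
$x = 1 - N_\ell / N_0$, which is scale-free and comparable between
fractions of different richness. Levels with fewer than `min_taxa = 50`
clusters are excluded — near the top of the tree the curve saturates at
100% and carries no information about the divergence rate. Two fractions'
slopes are compared by an F test on the interaction term of the pooled
regression; if the pooled fit has zero residual variance the comparison is
flagged degenerate instead of reporting a spurious p-value.

## Census, abundance relationship, differential screen

`overlap_census()` counts taxa shared between bulk and culturome within
each soil, between soils within each fraction, and the core present in
all four groups. `abundance_relationship_test()` regresses
$\log_{10}$ mean relative culturome abundance on the bulk value over taxa
present in both fractions and F-tests the slope; the pseudocount defaults
to half the smallest positive relative abundance in the dataset, so no
fixed constant can dominate low abundances.

`differential_screen()` is deliberately a simplified screen, not a
negative-binomial Wald analysis: median-of-ratios size factors (library
size factors, with a warning, if no taxon is observed in every sample), a
Welch t statistic per taxon on $\log_2(\text{normalised count} + 1)$, and
Benjamini-Hochberg adjustment (implemented as the explicit step-up and
cross-checked against `p.adjust`). It preserves the pipeline position and
FDR semantics while staying transparent; its p-values should be read as a
ranking device, not as a calibrated shrinkage analysis.

## The synthetic-community generator

`simulate_dataset()` produces a Yule tree scaled to unit height, bulk and
culturome counts for 2 soils x 6 replicates, and a per-taxon truth table.
Phylogenetic depths are expressed as fractions of tree height; clades "at
depth $q$" are cut by the same single-linkage machinery at cophenetic
threshold $2q$, tying the generative model to the inferential one.

The default configuration mirrors the study design the package targets:
600 taxa, 6 replicates per group, 20k reads per bulk sample, 30k per
culturome sample, log-normal base abundances ($\sigma = 1.5$).

*Soil differentiation* is generated by one process used for both
fractions: at four nested scales spanning $(0, q]$, each clade is knocked
out of one soil with a probability that halves with each coarser scale
(0.06 at the finest), and receives an opposite-signed log-normal abundance
shift (total $\sigma = 1$ split across scales, fine-weighted). Soil
endemism is thus a close-relative phenomenon, with attenuating clade-level
signal at deeper scales. Bulk soil runs this process at
`soil_effect_depth = 0.1`.

*The culturome* holds whole clades cut at `culturability_depth = 0.6`,
selected at random to cover about `culturable_clade_fraction = 0.25` of
the taxa — culturability is treated as a conserved clade-level trait
shared by both soils. Within those broad clades, which members actually
establish on the plates is idiosyncratic per soil: each member fails with
probability $0.45 \cdot \max(0, 1 - 3/\text{clade size})$, reflecting
within-clade competition from a composite inoculum. Competition produces
winners, not extinctions, so every culturable clade retains at least its
fastest-growing member in each soil, and a soil's culturome always keeps
at least one clade. Established taxa get fresh log-normal growth
potentials — cultivation success is decoupled from bulk abundance, which
is what produces the flat bulk-versus-culturome abundance relationship —
plus the clade-level differentiation process at `culturability_depth`,
and per-replicate log-normal amplification noise ($\sigma = 2$,
plate-to-plate variation). Counts are multinomial at the configured
depths, so samples sum exactly to their depth. Setting `bulk_coupling = 1`
with zero amplification noise and full culturability makes expected
culturome abundances proportional to bulk ones — a useful switch-off
limit for testing.

Under the defaults this reproduces the three qualitative signatures of
the motivating system: culturome rarefaction curves plateau much earlier
than bulk curves (observed richness ratio about 0.2); culturome
abundances do not track bulk abundances (median |Spearman rho| about
0.05); and the culturome divergence slope is roughly twice the bulk slope
— because the two culturomes share far fewer phylotypes at the leaf level
while both curves must reach 100% at the root.

What the generator does **not** emulate: sequencing error and chimeras,
taxonomy strings, overdispersed (non-multinomial) replicate noise in bulk
samples, spatial structure, or the real data's unknown dispersion
structure. Passing tests therefore demonstrate internal correctness and
qualitative fidelity, not quantitative agreement with any particular
soil dataset.

## Calibration results and a known limitation

On 100 seeded default simulations the full pipeline recovers the
culturome-versus-bulk slope contrast (culturome slope larger, interaction
p < 0.05) in well over 90% of runs.

We also examined the natural null configuration
`culturability_depth == soil_effect_depth`. The two fractions' curves are
then generated by the same differentiation process at the same depth, yet
the slope-comparison F test still rejects far more often than its nominal
level. The reason is structural, and worth understanding before using
`compare_slopes()` for inference on real data: the test treats the ~35
curve points as independent observations, but points along an
agglomeration ladder are strongly dependent (each level is a coarsening
of the previous one), and the dataset-to-dataset variability of a slope
— driven by which clades happen to carry the soil differences — is several
times larger than the within-curve residual error. The F test's p-value is
therefore well calibrated for independent noisy points (verified by
simulation) but anti-conservative across replicate datasets. Slope
comparisons between fractions of one dataset should be read as a
descriptive contrast with an optimistic p-value; confirmatory claims need
replicate-level variation (e.g. comparing slopes across independent
datasets or bootstrap samples).

## Numerical choices

* Permutation p-values use the add-one correction; seeds are explicit
  arguments everywhere randomness occurs.
* Single-linkage thresholds are closed ($d \le t$); ladder thresholds are
  deduplicated if quantiles tie.
* The UniFrac implementation accumulates subtree read sums in one
  postorder pass; it is cross-checked against an independent reference
  implementation to 1e-8 in the test suite.
* Welch statistics with zero pooled variance return statistic 0 (p = 1)
  for equal means and infinite statistic (p = 0) otherwise.
* Report JSON keeps non-finite statistics as explicit nulls with an
  `"undefined"` flag; counts round-trip exactly, branch lengths to 1e-12.
* Test problem sizes: the suite exercises the pipeline at 600 taxa for
  end-to-end recovery (100 seeds) and smaller instances (8-40 taxa) for
  the exhaustive and brute-force oracles, keeping the default run a few
  minutes long.

## Limitations

Beyond the slope-test calibration note above: the pipeline assumes a
single rooted tree covering the analysed taxa (taxa missing from the tree
are dropped, with a report, rather than grafted); the differential screen
is a transparent surrogate, not a replacement for a dispersion-modelling
analysis; and the synthetic generator's defaults are calibrated to
qualitative, not quantitative, fidelity.
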