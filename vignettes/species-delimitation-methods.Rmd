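---
title: "Methods: distances, barcode gaps, and four delimitation models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distances, barcode gaps, and four delimitation models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

This vignette explains the models behind `barcodegap`, the choices made
where the methods literature leaves room, and what the simulation-based
validation does and does not show about real data.

## Distances

All three distance models work from the same pairwise substitution tally:
sites where either sequence carries a gap or an IUPAC ambiguity code are
excluded for that pair only (*pairwise deletion*), transitions are A↔G and
C↔T, and everything else is a transversion. Ambiguity codes are treated as
missing rather than partially matched; this is the conservative convention
of the classic distance software and makes the tally exactly testable. The
p-distance is the mismatch proportion; JC69 applies
$-\tfrac34\log(1-\tfrac43 p)$; K2P applies
$-\tfrac12\log\big((1-2P-Q)\sqrt{1-2Q}\big)$ with separate transition ($P$)
and transversion ($Q$) proportions. Outside the logarithm's domain
($p \ge 3/4$, or $1-2P-Q \le 0$, or $1-2Q \le 0$, as happens between
saturated sequences) a distance is *undefined*: it is stored as `NA`,
excluded from downstream means, and counted in a warning — the analysis
continues, mirroring how practitioners treat "inapplicable" cells. No
gamma rate heterogeneity is offered; the plain K2P form is the one the
barcoding literature standardized on.

## The five divergence statistics

Given a distance matrix, true species labels, and a species-to-genus map,
per genus we report mean ± SD of:

* **average interspecific distance** — all heterospecific sample pairs in
  the genus, pooled. An option averages species-pair means instead; pooling
  is the default because it matches how whole-matrix summaries are usually
  produced.
* **smallest interspecific distance** — for each species, its minimum
  distance to any heterospecific congener (nearest neighbor), then averaged
  over species. A single scalar minimum could not produce the mean ± SD
  format these tables use, so the per-species nearest-neighbor reading is
  adopted; it is also the quantity of interest for identification.
* **average intraspecific distance** — conspecific pairs pooled over
  species with ≥ 2 samples.
* **mean theta** — each multi-sample species' average pairwise distance,
  averaged *with equal species weights*. This is the defensible reading of
  a "theta corrected for asymmetric sampling": a species sampled 20 times
  contributes exactly as much as one sampled twice. The exact
  individual-exclusion rule used by legacy software is not recoverable from
  published descriptions; equal weighting is deterministic and testable.
* **average coalescent depth** — mean over multi-sample species of the
  species' maximum intraspecific distance.

Interspecific fields are reported only for genera with ≥ 2 species, and
intraspecific fields only when some species has ≥ 2 samples; absent values
are `NA`, the analogue of a dashed table cell.

The **overlap region** is `[min(inter), max(intra)]` whenever the two
distributions cross, after rounding to 3 decimals (the resolution at which
such intervals are conventionally printed); its *total frequency* counts
intraspecific values at or above the lower bound plus interspecific values
at or below the upper bound. Unordered pairs are counted once.

## Trees

NJ trees come from the canonical Saitou–Nei agglomeration (ape's
implementation). Negative branch-length estimates — an artifact of NJ on
noisy matrices — are clamped to zero with the deficit moved to the sister
edge, so path lengths are approximately preserved and downstream methods
see non-negative lengths. Trees are midpoint-rooted: no outgroup is
assumed anywhere in the pipeline. Bootstrap support resamples alignment
columns with replacement, rebuilds the NJ tree, and scores each original
bipartition by its replicate frequency; a single seed controls all
replicates. The condensed tree collapses edges below a support cutoff
(default 50%) into polytomies.

GMYC needs a strictly ultrametric, bifurcating input. Rather than an
external rate-smoothing binary with unstated settings, we use mean-path-length
smoothing: each internal node is placed at its mean path length to its
descendant tips, and any parent that would sit at or below a child is
raised by ε = 1e-8 so no zero-length internal branch survives. An
already-ultrametric tree is a fixed point. This is a display/Input
transformation, not a dating method; node heights should not be
interpreted as ages.

## Delimitation

**Threshold clustering** is single-linkage: connected components of the
graph joining samples at distance strictly below the threshold (default
0.02, the aphid convention). Single linkage is primary because under a
clean barcode gap it coincides with reading clusters off the NJ tree and
it is oracle-testable; a tree-guided variant (maximal clades whose
internal distances all fall below the threshold) is exposed as
`threshold_cluster_tree()`. Undefined distances count as "no edge".

**ABGD.** The single-prior algorithm sorts all pairwise distances, takes
the largest distance not exceeding the prior `prior_p` as the
intraspecific limit, and finds the barcode gap as the first
consecutive-distance jump above that limit wider than `relative_gap_X`
(default 1.5) times the mean of up to 10 preceding jumps, falling back to
the widest jump above the limit. Samples are cut into single-linkage
components at the gap's lower edge, and the procedure recurses into every
component of ≥ 3 members until nothing splits; with no gap above the prior
in round one, everything stays in one group. Because a *single* large
prior sits above many genuine interspecific distances (and then the
recursion cannot split components whose internal distances all lie below
the prior), the default mode mirrors how the original web tool is used: a
scan of `n_prior_steps = 30` log-spaced priors from 0.001 to `prior_p`.
Every prior that lands inside the dominant barcode gap produces the same
partition, so the modal partition across the scan is the one stable over
the widest prior range; it is returned, with ties broken by gap prominence
(width relative to the divergence level at the gap's lower edge — the
multiplicative scale on which divergences live) and then by fewest groups.
The scan is finer than the classical 10-step web grid so this selection is
stable without a human reading the prior-vs-groups plot.

**GMYC (single threshold).** On an ultrametric tree with node heights
$h_1 > h_2 > \dots$, a candidate threshold $T$ splits events into
speciation (above) and coalescence (below, inside the clusters defined by
the branches crossing $T$). Each inter-event interval of duration $x$
contributes $r e^{-r x}$ with combined rate
$r = \lambda_1 k^{p_1} + \sum_j \lambda_2 (n_j(n_j-1))^{p_2}$, where $k$
is the number of species-level lineages and $n_j$ the lineage count inside
cluster $j$; the final interval to the present contributes survival only.
The four parameters are optimized (Nelder–Mead on log-rates) at every
candidate threshold (midpoints between consecutive node heights), and the
best threshold wins. The null model is a single coalescent over the whole
tree; the likelihood ratio is referred to χ² with 3 degrees of freedom
(the literature uses 2 or 3; 3 matches the parameter count difference and
is recorded in the fit object so users can re-refer the statistic). When
the test is not significant at α = 0.05 the returned partition is a single
group — on genuinely single-population data "one entity" is the
defensible answer even though some threshold always maximizes the
likelihood. GMYC input is the haplotype-collapsed tree (identical
sequences are zero-length cherries that violate the bifurcating
requirement); member samples are re-expanded into the output partition.

**PTP.** Branch lengths (in expected substitutions) are modeled as two
exponential classes: speciation-level branches, forming a rooted connected
subgraph containing the root, and within-species branches, the subtrees
hanging below "crown" nodes. Each class's ML rate is its reciprocal mean,
and the crown set is optimized by greedy hill-climbing over split/merge
moves from two deterministic starts (all singletons; the root's children)
plus 10 seeded random restarts. Branches shorter than `min_branch`
(default 1e-4, i.e. below a fraction of one substitution on a
barcode-length fragment) are excluded from the likelihood: a class
consisting of zero-length branches has unbounded rate, and without this
guard the ML solution degenerates to one "species" per haplotype. The
same consideration applies to the input tree, so the pipeline feeds PTP
the haplotype-collapsed NJ tree, exactly as the public delimitation
servers instruct users to remove identical sequences. Only the ML
delimitation is reported; Bayesian support values are out of scope.

## Concordance

A cluster is *accurate* if it equals one species' full sample set, *split*
if it is a strict subset of one species, *lumped* if it is a union of ≥ 2
complete species, and *partial lumped* otherwise (any multi-species
cluster with at least one incomplete species). The published four-category
scheme does not explicitly cover a cluster holding partial samples of
several species and no complete one; assigning it to *partial lumped*
keeps the categories exhaustive and the percentages summing to 100.
Percentages are of the number of estimated clusters, not of species.

## The simulator and what it validates

`make_benchmark()` composes three stages, each seeded from a documented
Lehmer step on the single user seed (so stages are reproducible
independently):

1. **Species tree**: backward Yule construction — with $k$ lineages the
   next (most recent remaining) split is $\mathrm{Exp}(b\,k)$ and the
   joining pair uniform, giving mean root height $\sum_{k=2}^{n} 1/(kb)$.
   `stem_depth` adds a constant to every node height, a floor on species
   divergence. A pure Yule tree cannot keep its shallowest split safely
   above a 2% threshold while its typical splits stay inside a narrow
   divergence band — the same exponential controls both the mean and the
   lower tail — whereas real barcode data sets of well-separated species
   have exactly such stems; `stem_depth = 0` recovers the pure process.
2. **Gene tree**: multispecies coalescent — within each species-tree
   branch, $k$ lineages coalesce at rate $\binom{k}{2}/N_e$ (so
   $E[T_2] = N_e$), survivors merge into the ancestral pool, and the root
   pool coalesces freely. No migration or hybridization.
3. **Sequences**: K2P substitution process (root uniform; per-branch
   closed-form transition matrix with ts/tv ratio κ and total rate
   `mutation_scale` per unit time), with independent per-base masking to
   `N` at `missing_fraction`. The process matches the K2P *distance* model
   exactly, so the distance estimator is unbiased for the simulation and
   parameter-recovery checks are clean.

The `"chaitophorus-like"` profile is 10 species × 5 samples, 658 bp,
`birth_rate = 16`, `stem_depth = 0.025`, `coalescent_Ne_scale = 0.0015`,
`kappa = 4`, `mutation_scale = 1` (so time is measured in expected
substitutions per site). These values were fixed once, by requiring the
*realized* statistics — not any delimitation outcome — to land in the
bands typical of densely sampled aphid barcode data: average intraspecific
K2P divergence in 0.001–0.02 and smallest interspecific distance in
0.06–0.14 for ≥ 90% of seeds, with the mean near 0.1. Problem sizes in the
test suite and acceptance script (50 bundles for the distance-based
methods, 15–20 for the tree-based ones, 500–1000 replicates for the
closed-form calibration checks) keep every check well inside interactive
runtimes while leaving Monte-Carlo error far below the tested margins.

What passing these checks shows: the implementations are internally
correct (oracle equivalence), the methods recover planted structure under
their own model assumptions, and the whole pipeline is deterministic under
a seed. What it does not show: performance on real data with rate
variation across lineages and sites, indels and alignment error,
introgression, or uneven geographic structure — none of which the
simulator emulates. In particular, simulated species whose coalescent
depth genuinely exceeds the barcode gap are "correctly" split by every
method here, just as geographically structured real species are; the
concordance report quantifies, not arbitrates, such cases.

## Numerical choices and edge cases

* Undefined distances: `NA`, never exceptions, except where a tree build
  genuinely cannot proceed (`nj_tree` names the offending pairs).
* Haplotype representative: first member in input order (deterministic
  tie-break); cross-species identical sequences keep the representative's
  label and are flagged.
* NJ negative branches: clamped to 0, deficit moved to the sister edge.
* Ultrametric enforcement: ε = 1e-8 minimum internal branch; the
  ultrametricity test tolerance is 1e-6 on root-to-tip spread.
* GMYC optimization: Nelder–Mead, 800 iterations, initialized from a
  method-of-moments coalescent rate; thresholds at height midpoints avoid
  ties between event classification and candidate placement.
* PTP ties: hill-climbing accepts only improvements > 1e-12; the
  one-species configuration is always evaluated explicitly.
* All percentages are of clusters; category counts always sum to the
  cluster count.

## Known limitations

Single-locus methods only (no multi-locus coalescent delimitation); no
maximum-likelihood tree search — tree-based methods accept any user tree
or the internal NJ tree; ABGD follows the published algorithm, not the
byte-level behavior of any particular executable; GMYC is single-threshold
only; PTP reports the ML solution without Bayesian support. Alignments are
assumed already built and trimmed.
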