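# barcodegap

DNA-barcoding species delimitation for aligned gene fragments (COI-style
mitochondrial barcodes, or any equal-length DNA alignment with per-sample
species labels). The package is aimed at taxonomists and molecular
ecologists who want to run the standard single-locus delimitation toolkit —
and score it against morphological identifications — in one reproducible R
pipeline, with a calibrated simulator to validate every stage offline.

## What it computes

**Distances.** Pairwise p, Jukes–Cantor (JC69) and Kimura 2-parameter (K2P)
distances under pairwise deletion (a site is dropped for one pair only when
that pair has a gap or ambiguity there). K2P separates the transition
proportion *P* from the transversion proportion *Q*:

    d = -1/2 · ln( (1 - 2P - Q) · sqrt(1 - 2Q) )

**Divergence statistics.** The five classical inter/intra-specific metrics,
per genus: average interspecific distance (pooled heterospecific pairs),
smallest interspecific distance (per-species nearest neighbor, averaged),
average intraspecific distance (pooled conspecific pairs), mean theta
(per-species average pairwise distance, species weighted equally to counter
asymmetric sampling), and average coalescent depth (mean of per-species
maximum intraspecific distance). Plus a barcode-gap *overlap region*
analysis: the interval [min(inter), max(intra)] and the number of distance
values falling inside it — the pairs a fixed threshold could not identify.

**Delimitation, four ways.**

* *threshold*: single-linkage clustering at a distance threshold (2% is the
  aphid convention);
* *ABGD*: Automatic Barcode Gap Discovery — ranked-distance gap detection
  beyond a prior intraspecific limit, recursive re-partitioning, and a
  multi-prior scan that returns the partition stable over the widest prior
  range;
* *GMYC*: single-threshold General Mixed Yule Coalescent likelihood on an
  ultrametric tree (Yule branching above the threshold, per-cluster
  coalescents below; likelihood-ratio test against a one-population null);
* *PTP*: Poisson Tree Processes — two exponential branch-length classes
  (speciation vs within-species) optimized over "crown" placements.

**Concordance.** Every estimated cluster is scored against the reference
species as *accurate* (exact match), *split* (strict subset of one
species), *lumped* (union of complete species) or *partial lumped* (mixed),
with Table-style counts and percentages.

**Simulator.** Yule species tree (optionally with deep species stems) →
multispecies-coalescent gene tree → K2P sequence evolution with optional
missing data, plus the truth partition; the `"chaitophorus-like"` profile
is calibrated so realized intraspecific K2P divergence falls in 0.001–0.02
and the smallest interspecific distance in 0.06–0.14, the structure typical
of densely sampled aphid barcode studies.

## Worked example

```r
library(barcodegap)

b  <- make_benchmark(sim_profile(seed = 1))   # 10 species x 5 samples, 658 bp
dm <- distance_matrix(b$alignment, "k2p")

five_metrics(dm, b$truth)
#   avg_interspecific_mean smallest_interspecific_mean avg_intraspecific_mean
#                   0.1495                      0.0849                 0.0035
#   mean_theta_mean avg_coalescent_depth_mean
#            0.0035                     0.007

threshold_cluster(dm, 0.02)          # -> 10 clusters
res <- abgd_partition(dm, abgd_config(prior_p = 0.1))
res$gap_distance                     # -> 0.033 (the detected barcode gap)

concordance_report(res$partition, b$truth)
# concordance: 10 clusters vs 10 morphospecies
#   accurate 10 (100.00%)  split 0 (0.00%)  lumped 0 (0.00%)  partial lumped 0 (0.00%)
```

The divergence numbers read like a row of a barcoding summary table: within
this simulated "genus" the nearest heterospecific sample is on average 8.5%
divergent while conspecific samples differ by 0.35%, a clean barcode gap —
which both distance-based methods then find, reproducing the planted
10-species partition exactly.

For real data, `read_alignment("aln.fasta", "metadata.tsv")` loads a FASTA
alignment plus a TSV with `sample_id`, `species`, `genus` columns, and
`run_pipeline(run_config(...))` runs everything per gene (distances,
metrics, bootstrapped NJ tree with 50% condensation, all four methods,
concordance) and writes TSV/JSON/newick artifacts.

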