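# pgpan

Habitat-resolved pan-genome and functional profiling of plant
growth-promoting bacteria (PGPB).

Strain collections of PGPB span habitats — leaf-associated (LA),
soil-associated (SA) and other/control environments (OA) — and the
question for comparative genomics is whether habitat leaves a signature
in the genomes: size and GC content, gene-family repertoires,
carbohydrate-active enzymes (CAZymes) and secondary-metabolite
biosynthetic gene clusters (BGCs). `pgpan` packages that analysis as
tested, composable stages plus a synthetic-cohort generator with planted
truth, so every stage is verifiable without genome downloads.

## What it computes

* **Genome QC**: completeness/contamination filter (keep when
  completeness ≥ 95 %, contamination ≤ 5 %) and ANI dereplication — two
  genomes are redundant when ANI ≥ 99.9 % and both directional coverages
  > 95 %; redundancy components keep one seeded-random representative.
* **Phylogeny**: Newick I/O, cophenetic distances
  `d(i,j) = depth(i) + depth(j) − 2·depth(MRCA(i,j))`, a neighbor-joining
  builder, single-copy core-family extraction.
* **Clustering**: PAM k-medoids (deterministic BUILD+SWAP) on cophenetic
  distances; k chosen by the highest mean silhouette
  `s(i) = (b(i) − a(i)) / max(a(i), b(i))` over k = 2…20; complete-linkage
  clustering of per-Mb feature profiles; habitat composition and
  majority-habitat concordance tables.
* **Pan-genome**: partition of orthogroup families into core (in every
  strain), unit-specific (confined to one taxon × habitat unit) and
  accessory; phylogenetically matched habitat subsampling; per-group
  family-abundance tables.
* **Profiles**: protein-to-family assignment by best-hit global-alignment
  identity (Needleman–Wunsch, match +1 / mismatch 0 / gap −1) with the
  strict > 40 % identity rule; class counts (GH, GT, CE, AA, CBM, PL and
  BGC classes) and per-megabase normalisation.
* **Statistics**: pooled Student's t, one-way ANOVA with significance
  tiers, PCA, Brownian-motion phylogenetic PCA, PERMANOVA (Adonis,
  pseudo-F with `p = (1 + #{F_perm ≥ F_obs})/(1 + n_perm)`), and a
  habitat-enrichment scan over feature classes.

## Worked example

```r
library(pgpan)

cfg <- sim_config(n_strains_per_habitat = c(LA = 20, SA = 20, OA = 15),
                  n_core = 40, n_accessory = 60, n_specific = 30, seed = 7)
cohort <- simulate_cohort(cfg)
cohort
#> synthetic cohort: 55 strains (LA 20, OA 15, SA 20), 130 gene families, 18 feature classes

report <- run_pipeline(pipeline_config(sim = cfg, k_max = 6,
                                       n_perm = 999, seed = 3))
report
#> pipeline report
#>   QC: 55 genomes in, 50 kept (0 quality, 5 redundant removed)
#>   clustering: k_best = 3 (mean silhouette 0.865)
#>   pan-genome: 128 families (core 40 [31.25%], accessory 60 [46.88%], specific 28 [21.88%])
#>   PERMANOVA habitat effect: pseudo-F = 99.792, p = 0.001
```

Reading the output: the 5 planted near-duplicate genomes are removed by
dereplication; silhouette-based selection finds the three planted habitat
clades (mean silhouette 0.865); the pan-genome partition returns the
planted class counts on the surviving strains (two planted unit-specific
families lost their carriers to dereplication); and habitat structure in
the per-Mb feature profiles is detected at the permutation floor
p = 1/(999 + 1) = 0.001.

Printed-table arithmetic works directly on published counts, e.g. the
share of each habitat's strains that cluster with their majority habitat
in a 573-strain cohort:

```r
share_pct(c(168, 251, 81), 573)
#> [1] 29.32 43.80 14.14
```

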