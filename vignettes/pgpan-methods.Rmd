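---
title: "Methods: habitat-resolved pan-genome and functional profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat-resolved pan-genome and functional profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgpan)
```

## The analysis

`pgpan` implements a comparative-genomics pipeline for bacterial strain
collections annotated with a habitat — leaf-associated (LA),
soil-associated (SA) or other (OA) — as is typical for plant
growth-promoting bacteria (PGPB). The question the pipeline addresses is
whether habitat leaves a signature in genome composition: genome size and
GC content, gene-family (orthogroup) repertoires, carbohydrate-active
enzymes (CAZymes) and secondary-metabolite biosynthetic gene clusters
(BGCs).

The stages, each usable on its own:

1. **Genome QC** — keep genomes with completeness ≥ 95 % and
   contamination ≤ 5 %; treat two genomes as functionally redundant when
   ANI ≥ 99.9 % and both directional coverages exceed 95 %, close the
   redundancy relation into connected components, and keep one
   representative per component (seeded uniform draw).
2. **Phylogeny** — consume a Newick strain tree (or build a
   neighbor-joining tree from any distance matrix) and convert it to a
   cophenetic (patristic) distance matrix,
   `d(i,j) = depth(i) + depth(j) − 2·depth(MRCA(i,j))`.
3. **Clustering** — PAM k-medoids (classic BUILD + SWAP) on the
   cophenetic matrix, with k chosen by the highest mean silhouette over a
   scan (default 2–20); habitat composition per cluster and
   majority-habitat concordance of the whole cohort; complete-linkage
   hierarchical clustering of per-Mb feature profiles.
4. **Pan-genome** — partition gene families into core (present in every
   strain), unit-specific (non-core, confined to one taxon × habitat
   unit — the petals of a flower plot) and accessory (everything else);
   phylogenetically matched subsampling to balance habitat panels for
   core-genome comparison.
5. **Profiles** — assign proteins to reference families by best-hit
   global-alignment identity with a strict > 40 % rule, count hits by
   class (GH, GT, CE, AA, CBM, PL; BGC classes), and normalise per
   megabase of genome.
6. **Statistics** — pooled Student's t (LA vs SA within each taxon),
   one-way ANOVA (across taxa within each habitat), PCA and
   phylogenetic PCA, and PERMANOVA (Adonis) with seeded permutations.

## Models and numerical choices

**Dereplication.** "Coverage" between two genomes is directional; the rule
here requires the *minimum* of the two coverages to exceed 95 % — the
conservative symmetric reading. The ANI bound is inclusive, the coverage
bound strict. Pairwise redundancy is closed transitively (chains and
triangles collapse to one representative), since near-identity behaves as
an equivalence in practice.

**PAM.** The BUILD phase greedily accumulates medoids by largest objective
decrease; the SWAP phase applies the single best strictly improving
(medoid, non-medoid) exchange per sweep until none remains. Exact ties
break lexicographically by strain id, which makes the procedure fully
deterministic. BUILD + SWAP is a local search: its converged objective is
swap-optimal (no single exchange improves) but on a minority of instances
sits above the exhaustive optimum — the canonical `cluster::pam`
converges to the same local optima, which the test suite checks
explicitly. The silhouette is undefined at k = 1, so the selection scan
runs over k = 2…20 (points in singleton clusters contribute 0).

**Matched subsampling.** The published description of phylogenetically
balanced habitat panels mixes a random draw with a deterministic
least-deviant choice. The rule implemented here is one consistent
generalisation: the reference habitat contributes all its strains (or a
seeded draw of `n_per_group`); every other habitat contributes the
`n_per_group` candidates whose mean cophenetic distance to the reference
panel deviates least from the grand mean of candidate means. This
demonstrably reduces the variance of mean-distance-to-reference relative
to uniform subsampling (a property test covers it).

**Unit-specific families.** "Strain-specific" genes in a flower plot are
per petal, i.e. per taxon × habitat unit, not per individual strain; a
family is unit-specific when it is absent from at least one strain
overall and all its carriers share one unit. With a single unit this
definition collapses (every non-core family is confined to the unit);
the generator therefore refuses to plant accessory families without at
least two units.

**Alignment identity.** Family assignment scores a Needleman–Wunsch
global alignment with match +1, mismatch 0 and linear gap −1; identity is
matched columns over all alignment columns, gaps included. The scheme is
deliberately transparent rather than BLOSUM-weighted: the 40 % keep rule
is about a coarse identity band, and an exact, enumerable score makes the
threshold and its strictness (> 40, not ≥ 40) testable against brute
force. `X` residues never match. Traceback prefers diagonal, then up,
then left, so tied optima resolve deterministically.

**PERMANOVA.** Anderson's pseudo-F on the Gower-centred squared distance
matrix, with the +1 permutation convention
`p = (1 + #{F_perm ≥ F_obs}) / (1 + n_perm)`; the smallest attainable p
is therefore 1/(n_perm + 1) — 0.001 at the default 999 permutations. No
distance metric is imposed: cophenetic and Euclidean-on-per-Mb-features
matrices are both accepted.

**Phylogenetic PCA.** The term is used here in the Brownian-motion GLS
sense: tree covariance `C_ij =` shared root-to-MRCA path length, GLS mean
`a = (1ᵀC⁻¹1)⁻¹1ᵀC⁻¹X`, covariance `(X−1a)ᵀC⁻¹(X−1a)/(n−1)`, then an
eigen-decomposition. On a star tree with unit tip branches C = I and the
result equals ordinary PCA exactly — the suite asserts this to 1e-8.
Component signs follow the convention that each component's
largest-magnitude loading is positive.

**Multiple testing.** The enrichment scan reports raw p-values as primary
(mirroring common practice for per-panel star annotations) and appends a
Benjamini–Hochberg column per scan for reuse. Significance tiers: `*`
0.01 < p ≤ 0.05, `**` 0.001 < p ≤ 0.01, `***` 0.0001 < p ≤ 0.001, `****`
p ≤ 0.0001.

**Rounding.** Printed percentage shares use round-half-up to two
decimals (`round_half_up()`), matching how cohort tables are normally
typeset; base `round()` rounds half to even and disagrees on exact ties.

## The synthetic-data generator

`simulate_cohort()` produces cohorts with the statistical structure the
analysis assumes, so the whole pipeline is testable without downloads.
Defaults encode the study conditions: 195/283/95 strains (LA/SA/OA), mean
genome sizes 4.67/6.08/5.97 Mb, mean GC 63.27/57.12/56.95 %.

Free parameters with no published value were fixed once at values a
microbial comparative genomicist would call realistic, and are not
revisited:

* size SD 0.8 Mb (LA) / 1.2 Mb (SA, OA); GC SD 3 percentage points —
  unimodal spreads comparable to the within-habitat spread of real
  genome-size densities;
* per-Mb CAZyme rates giving SA > OA > LA per-genome totals in the
  low-hundreds (roughly 100–400 per genome, the range reported for soil
  and leaf bacteria); modest BGC class rates (~5–15 clusters per genome)
  with soil-leaning enrichment except terpene and β-lactone;
* orthogroup structure 163 core / 378 accessory / 212 specific — the
  published flower-plot partition scaled down 100-fold — with 14 core
  families planted single-copy;
* trees are Yule (pure birth, unit rate) per habitat clade, rescaled to
  unit height and joined by stem branches of length 4 (the
  `clade_separation`), giving a between/within separation where
  silhouette-based selection is expected to work.

Sizes and GC are truncated normals (sizes at 0.5 Mb, GC to (20, 80));
feature counts are Poisson with mean `rate × Mb`; planted redundant pairs
get ANI ≥ 99.9 % and coverages > 95 % while background pairs fail at
least one threshold; toy proteins are reference sequences with point
substitutions only (no indels), adjusted until the global identity lands
within ±2 points of the target, which keeps the identity oracle exact.

What the generator does **not** emulate: nucleotide sequences (and hence
real ANI estimation), tree-inference error, orthology-inference error,
correlated feature classes, geographic structure. Passing recovery tests
therefore shows the pipeline's logic is correct under its own model
assumptions, not that those assumptions hold for any particular real
collection.

## Problem sizes in the tests

The suite and the acceptance script run on desk-scale instances chosen as
the package's own test design: cohorts of 30–60 strains, 90–130 gene
families, planted 4-clade trees of 40 tips, 50-strain-per-group
enrichment panels, 500-replicate null calibrations at 199 permutations,
and brute-force oracles at n ≤ 12 (PAM), ≤ 20 leaves (cophenetic) and
≤ 8 residues (alignment enumeration). Printed-table arithmetic (partition
shares, cluster composition, concordance) is exact and scale-free.

## Known limitations

* No sequence-based tree inference or orthology inference: trees and
  orthogroup matrices are inputs (or simulated).
* PAM is exact local search, not an exhaustive optimiser; for cohorts far
  beyond ~10³ strains a CLARA-style variant would be needed.
* The pairwise alignment is O(L²) per pair in plain R; it is meant for
  the desk-scale reference databases used here, not proteome-scale
  screens.
* BGC detection is consumed as class-count tables; no cluster-finding
  logic is included.
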