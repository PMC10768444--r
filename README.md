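# tcrdiv

Analysis of T-cell receptor (TCR) repertoire diversity from targeted
genomic DNA sequencing, for immunologists and biostatisticians asking
whether donor groups (e.g. disease cases versus controls) differ in their
T-cell clonal structure.

Somatic V(D)J recombination makes nearly every TCR junction unique, so a
donor's repertoire is summarised by a table of **clonotypes** — a CDR3
nucleotide sequence plus its V, (D,) and J segments — with molecule counts
obtained by UMI deduplication. The package implements the full chain:

* **Read → clonotype calling**: Phred/length QC, validation-barcode
  demultiplexing, 12 bp fragment-UMI parsing, exact 20-base tag scanning
  (with rtag/alt-tag disambiguation of homologous segments), CDR3
  extraction at predicted RSS cleavage points (or earlier germline
  divergence), single-ORF productivity filtering, and degenerate UMI
  deduplication allowing up to two mismatches.
* **Diversity**: Rényi entropy profiles
  `H_a = log(sum p_i^a) / (1 - a)` over an order grid (default `[0,10]`,
  step 0.2; `H_0` = log-richness, `H_1` = Shannon, large `a` →
  Berger–Parker), with pairwise Euclidean profile distances after randomly
  down-sampling the deeper sample of each pair to equal depth.
* **Visualisation**: classical (Torgerson) multidimensional scaling of the
  distance matrix.
* **Classification**: the Potential SVM for relational data — a sparse,
  box-constrained `l1`-penalised margin model applied directly to the
  (non-PSD) distance matrix — with leave-one-out cross-validation,
  class-size-preserving label-permutation p-values, and Bonferroni
  hypothesis families (18 primary tests at 0.05/18 ≈ 0.0028; secondary
  aims at 0.05/54 ≈ 9.3e-4).
* **Simulation**: synthetic germline references, clonally expanded
  repertoires (singletons + shifted-geometric expanded clones), cohorts
  with a tunable group effect, and UMI-tagged 2×250 bp read pairs — ground
  truth for every stage, so the whole pipeline is testable without any
  external data.

## Worked example

Simulate a cohort in which group B carries extra clonal expansion, build
the profile-distance matrix, and test the separation:

```r
library(tcrdiv)

cs <- cohort_spec(groups = c(A = 20, B = 20), base_expansion = 0.05,
                  effect_delta = 0.3, effect_groups = "B",
                  depth_range = c(1e3, 1e4), seed = 42)
cohort <- simulate_cohort(cs)
D <- distance_matrix(cohort_counts(cohort), grid = alpha_grid(), seed = 7)
y <- ifelse(cohort$group == "A", 1, -1)
permutation_test(D, y, n_perm = 199, seed = 9)
#> <classification_result> comparison: balanced accuracy 0.900, p = 0.005 (199 permutations)
```

Leave-one-out classification recovers 90% balanced accuracy and no label
shuffle matches it, so `p = (1 + 0)/(1 + 199) = 0.005` — the groups
separate well below the 1% level. On a null cohort (`effect_delta = 0`)
the same pipeline gives chance-level accuracy and a large p-value
(`analysis/05_classify.R` prints `balanced accuracy 0.425, p = 0.6750`
for its null cohort).

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01_simulate.R` (cohorts) → `02_call_clonotypes.R` (read-level
demo; recovers 100% of truth clonotype counts error-free) →
`03_diversity_distances.R` → `04_mds.R` → `05_classify.R`, writing tables
under `results/`.

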