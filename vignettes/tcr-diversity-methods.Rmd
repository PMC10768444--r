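---
title: "Methods: TCR repertoire diversity profiles and relational classification"
author: "tcrdiv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TCR repertoire diversity profiles and relational classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrdiv)
```

# The scientific problem

T cells recognise antigen through receptors assembled by somatic V(D)J
recombination. Random trimming and non-templated insertion at the CDR3
junction make almost every receptor sequence unique, so a blood sample's
set of *clonotypes* — here a CDR3 nucleotide sequence together with its V,
(D,) and J segments, without chain pairing — is a fingerprint of that
donor's T-cell compartment. Antigen-driven clonal expansion distorts the
clone-size distribution: most clonotypes are seen once, a minority many
times. The question this package operationalises is whether such
distortions differ systematically between donor groups (for instance,
disease cases versus controls), given clonotype tables derived from
targeted genomic DNA sequencing of the TCR α, β and γ loci (δ is excluded:
recombination of the α locus deletes TCR-δ, so δ-chain counts are not
comparable across samples).

The pipeline has five stages, each usable on its own:

1. **simulation** (`make_germline_reference()`, `simulate_repertoire()`,
   `simulate_cohort()`, `simulate_reads()`) — synthetic ground truth for
   every later stage;
2. **clonotype calling** (`qc_filter()`, `demultiplex_and_parse_umi()`,
   `scan_tags()`, `call_cdr3()`, `assess_productivity()`, `dedup_umis()`,
   `build_repertoire()`) — reads to per-sample clonotype count tables;
3. **diversity** (`renyi_entropy()`, `diversity_profile()`,
   `downsample_counts()`, `distance_matrix()`) — count tables to a
   between-sample distance matrix;
4. **embedding** (`classical_mds()`, `plot_embedding()`) — visualisation;
5. **classification** (`train_psvm()`, `psvm_loocv()`,
   `permutation_test()`, `hypothesis_family()`, `run_comparison_grid()`) —
   statistical assessment of group separation.

# Diversity model

## Rényi entropy profiles

For a sample with clonotype frequencies \(p_1, \dots, p_K\), the Rényi
entropy of order \(\alpha \ge 0\) is

\[ H_\alpha = \frac{1}{1-\alpha} \log \sum_{i=1}^{K} p_i^{\alpha}, \]

with \(H_0 = \log K\) (log-richness), \(H_1 = -\sum_i p_i \log p_i\)
(Shannon, taken as the direct limit rather than numerically), and
\(H_\infty = -\log \max_i p_i\) (Berger–Parker regime, dominated by the
largest clone). A single order would compress the clone-size distribution
to one number; the *profile* — \(H_\alpha\) evaluated on a grid of orders —
retains the whole shape: low orders weight rare clonotypes, high orders
expanded ones. Profiles are non-increasing in \(\alpha\), a property the
test suite checks on random vectors.

Entropies are in nats (natural log). The unit cancels from all relative
comparisons; it only scales the distances uniformly.

The default grid is \([0, 10]\) in steps of 0.2 (51 points); a finer
\([0, 20]\)/0.1 grid (201 points) is available for sensitivity analysis.
Orders within \(10^{-9}\) of 1 are snapped to the Shannon form to avoid
catastrophic cancellation in \(1/(1-\alpha)\). Very low orders are the
least stable under sampling noise — a caveat inherited by any
profile-based distance.

## Depth equalisation

Rearrangement counts vary over orders of magnitude between libraries, and
every entropy order except \(\alpha = 1\) is depth-biased. Before two
samples are compared, the deeper one is randomly down-sampled **without
replacement** (multivariate hypergeometric) to the shallower one's depth;
the shallower sample is used as-is. The pair distance is then the
Euclidean norm of the difference between the two profiles over the grid.
By default a single down-sampling draw is used per pair;
`n_replicates` can average several draws, which reduces the draw noise at
proportional cost (the single-draw default reflects the straightforward
reading of a one-shot down-sampling step, and the draw noise is small
relative to between-sample differences at the depths used here).

Each pair's random draw is seeded by a hash of the master seed and the
*sorted* pair of sample ids, making the matrix symmetric, reproducible and
invariant to the order in which samples are supplied.

"All chains considered together" is implemented as concatenation of the
per-chain profiles, which for Euclidean norms is identical to the square
root of the summed squared per-chain distances
(`combine_chain_distances()`). The combination rule is a package choice;
concatenation is the simplest rule that treats every chain's profile
point symmetrically.

# From reads to clonotypes

The caller re-implements a tag-based strategy specialised to targeted gDNA
libraries in which each read pair begins with a 4 bp validation barcode, a
6 bp random UMI and a 4 bp library ID:

* **QC** — every base of both mates must exceed Phred 20 and each mate
  must be at least 250 bp. The length rule is interpreted as
  \(\ge 250\) because a 2×250 protocol cannot produce longer reads.
* **Demultiplexing** — validation barcodes must match on both mates; the
  two 6 bp UMIs concatenate (mate 1 first; any fixed order works, this one
  is the package's convention) into a fragment-specific 12 bp UMI carried
  by both derived single-end reads.
* **Tag scanning** — every V/D/J element is identified by exact matches to
  20-base tags positioned 15 bp from its predicted RSS cleavage site, with
  separate tags for the coding and signal flanks, on both strands. Tags
  shared by homologous elements (rtags) are resolved by secondary alt-tags
  at the nearest point of sequence divergence; a read matching an rtag but
  no single alt-tag is reported ambiguous rather than guessed. Allelic
  variants are handled as alternative tag versions — matching stays exact.
* **CDR3 extraction** — from each tag the caller walks toward the
  predicted cleavage point comparing read to germline; the junction
  boundary is the cleavage point, or the first divergence if it occurs
  earlier (the signature of exonuclease trimming). The CDR3 is the read
  sequence between the V and J boundaries; it may legitimately be empty.
  Junction identity is therefore a *canonical function of the sequence*:
  the simulator records its truth junctions with the same walk, so
  error-free round trips recover truth exactly rather than to within an
  alignment convention.
* **Productivity** — a cassette is productive when the junction length
  carries the V frame into the J segment's annotated frame and the single
  ORF across the assembled V-CDR3-J contains no stop codon. Only
  productive coding joints enter repertoires; signal-joint conformations
  are recorded but excluded, and δ-locus calls are dropped.
* **UMI deduplication** — within one clonotype of one sample, UMIs within
  Hamming distance 2 are merged. Merging is single-linkage (union-find
  over the ≤2-mismatch graph), so the molecule count equals the number of
  connected components; this is deterministic, independent of input order,
  and exactly matches the brute-force components oracle the tests enforce
  on all small instances. Identical clonotypes with distinct UMIs are what
  the pipeline scores as clonal expansion.

Every input read pair is accounted for in exactly one bin
(`qc_fail`, `validation_fail`, `undetermined`, `no_call`, `called`), and
bin totals must sum to the input count — a conservation invariant the
tests check after deliberately corrupting reads.

# The synthetic-data module

The simulator provides ground truth at three levels, and its defaults are
the study conditions the rest of the package assumes:

* **Germline references** — toy loci with 8 V / (2 D) / 4 J segments per
  locus, V coding regions of 100 bp with 40 bp signal flanks (J mirrored;
  D a 12 bp core between two 40 bp flanks), annotated RSS cleavage points
  and coding frames, stop-free germline coding regions, and sequences
  redrawn until all tag regions are unique. These sizes keep a full
  junction inside a 250 bp read while leaving room for exhaustive oracles.
* **Repertoires** — clone sizes are a mixture of singletons and expanded
  clones whose sizes follow a shifted truncated geometric law
  \(P(S = k) = q(1-q)^{k-2},\ k \ge 2\): a single-parameter heavy tail
  with a closed-form pmf, which makes goodness-of-fit testable. The
  expanded fraction is the biological knob; singleton clonotypes fill the
  remaining molecule budget so the total rearrangement count is exact.
  Default \(q = 0.2\) (mean expanded clone size 6).
* **Cohorts** — per-sample depths are drawn log-uniformly, by default over
  \([10^3, 10^5]\) (rearrangement counts spanning two orders of
  magnitude); a group effect adds `effect_delta` to the expansion fraction
  of designated groups only, so `effect_delta = 0` yields exchangeable
  groups — the calibration null.
* **Reads** — each molecule becomes a fragment (the junction cassette
  padded into the 250–350 bp sonication range) with a fresh 12 bp UMI;
  PCR copies are Poisson-distributed and carry the molecule's UMI with at
  most `umi_error_max` ≤ 2 substitutions; uniform substitution errors at
  `error_rate`. The segment and fragment geometry guarantees that each
  molecule's junction is recoverable from at least one mate.

What the simulator does **not** emulate: real IMGT germline content and
allele frequencies, thymic selection, position-dependent or indel
sequencing errors, PCR chimeras, and cross-sample index hopping. Passing
tests therefore demonstrate the pipeline's internal correctness and
statistical calibration under the stated generative model, not robustness
to every artefact of real libraries.

# Classification on distances

## Why a relational classifier

A distance matrix is not a kernel: it is not positive semi-definite, and
its rows are sample-by-reference relations rather than feature vectors.
The Potential Support Vector Machine family of methods handles exactly
this *dyadic* setting by treating each reference column as a potential
feature and selecting a sparse, bounded set of them. The package
formulates the fit as

\[ \min_{\boldsymbol\alpha,\,b}\ \tfrac12 \lVert X\boldsymbol\alpha + b\mathbf{1} - \mathbf{y} \rVert^2
   + \varepsilon \lVert \boldsymbol\alpha \rVert_1
   \quad \text{s.t.}\ |\alpha_j| \le C, \]

where \(X\) is the relational matrix with columns standardised to zero
mean and unit variance, \(\mathbf{y}\) the ±1 labels, and prediction is
\(\mathrm{sign}(\sum_j \alpha_j K(x, j) + b)\). The \(\ell_1\) term prunes
reference columns (the "support" samples); the box bounds each column's
influence.

Two interchangeable backends solve this convex QP: the package's own
cyclic coordinate descent (soft-threshold and clip, with warm starts
across leave-one-out folds) and `glmnet` as a generic penalised
least-squares backend, which is markedly faster on larger strongly
correlated instances. `solver = "auto"` switches at 20 reference columns.
Both are validated against each other and against an independent
box-constrained L-BFGS-B oracle on the positive/negative variable split.

## Hyperparameters

\(\varepsilon\) defaults to \(0.1 \cdot \max_j |X_j^\top(\mathbf{y} -
\bar{y})|\) — one tenth of the smallest penalty that zeroes every
coefficient — computed from the training fold only, so the default adapts
to scale without leaking test information. \(C\) defaults to 100, a
loose box that mainly guards against degenerate blow-ups. An inner-fold
grid search could tune both, but at permutation × LOOCV scale it
multiplies cost by the grid size for little benefit on the simulated
cohorts, so the fixed leakage-free default is the package's choice and
any tuning is left to the user-facing `train_psvm()` interface.

## LOOCV and the permutation test

Performance is estimated by leave-one-out cross-validation in which the
held-out sample is removed *both* as a row and as a reference column —
otherwise its own distances would leak into training. The score is
balanced accuracy (mean of per-class recalls), robust to the unequal
group sizes that QC exclusions produce.

Significance comes from label permutations that preserve class sizes: the
full LOOCV is re-run per shuffle and

\[ p = \frac{1 + \#\{\text{shuffles scoring} \ge \text{observed}\}}{1 + B} \]

(the add-one estimator, which cannot return zero). "Scoring at least the
observed" is evaluated lexicographically on (balanced accuracy, mean
margin \( \overline{y f(x)} \)): balanced accuracy on a handful of samples
is coarsely discrete, and counting whole tie-groups would make \(p\)
grossly conservative; the continuous margin tie-break restores a
near-exact null (the p-value uniformity suite — 200 replicate null
cohorts, Kolmogorov–Smirnov at the 1% level — is what holds this honest).
The reported score remains the balanced accuracy. A wall-clock budget can
truncate a run; truncated results are flagged and their \(p\) computed
over the completed shuffles.

## Families and multiplicity

`hypothesis_family()` enumerates the study design: three primary
hypotheses (ME vs HC, ME vs MS, MEsa vs MEmm), each tested for two cell
types and three chains — 18 tests at threshold \(0.05/18 \approx 0.0028\)
— and six secondary pairings (36 tests) corrected against all 54 tests at
\(0.05/54 \approx 9.3 \times 10^{-4}\). The pooled "Cases" group of the
secondary family is configurable because two readings exist (all disease
cases, or ME only); the default pools MEsa + MEmm + MS and the
alternative is one argument away.

# Numerical and degenerate-input choices

* Orders within \(10^{-9}\) of 1 use the Shannon formula directly.
* Constant relational columns get infinite scale (zero contribution)
  rather than dividing by zero.
* Classical MDS dimensions with non-positive eigenvalues — which arise
  when down-sampling noise makes the matrix slightly non-Euclidean — are
  clipped with a warning, the classical-scaling convention; embeddings are
  only ever compared through pairwise distances, never coordinates.
* Decision values of exactly zero predict the positive class (a fixed,
  measure-zero convention).
* Down-sampling, pair seeds, per-stage seeds and permutations all derive
  from one master seed via a deterministic string hash kept below
  \(2^{31}\), so every table is bit-reproducible.
* UMI dedup rejects UMIs that are not 12 bp; repertoire construction
  rejects mixed sample ids; `simulate_repertoire()` rejects infeasible
  specifications (more clonotypes than molecules).

# Problem sizes

The shipped analyses and tests run at desk scale, chosen so each suite
completes in minutes while retaining statistical power: detection uses 20
replicate cohorts of 2 × 20 samples with depths in \([10^3, 10^4]\) and
199 permutations; calibration uses 200 replicate null mini-cohorts of
2 × 6 samples with 99 permutations; read-level round trips use tens of
clonotypes and a few hundred read pairs. Sequence-level cohort simulation
scales linearly and is exercised on small cohorts; count-level simulation
is the default for cohort-scale statistics.

# Known limitations

* Tag matching is exact; heavily mutated or somatically altered tag
  regions would drop reads rather than mis-assign them.
* D-segment identification inside a coding joint requires the intact
  12 bp core; trimmed D cores yield `d_call = NA`, collapsing clonotypes
  that differ only in D usage.
* The geometric expansion law is a deliberately simple stand-in for real
  clone-size distributions, which are better described by power laws with
  sampling distortion; conclusions about power transfer only
  qualitatively.
* Balanced accuracy on small groups is coarse; the margin tie-break fixes
  the null calibration but the score itself remains a blunt effect-size
  summary.
* LOOCV scores under the null sit slightly below 0.5 (the usual
  pessimistic bias of leave-one-out with dependent folds); inference
  should always go through the permutation p-value, never the raw score.
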