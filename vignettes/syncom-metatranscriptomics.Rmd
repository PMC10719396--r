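---
title: "Strain-resolved SynCom metatranscriptomics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-resolved SynCom metatranscriptomics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncomtx)
```

This vignette is the package's own account of its models: what is computed,
under which assumptions, which knobs matter, and where the design was
genuinely open. Nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## 1. The measurement model

A synthetic community (SynCom) of genome-sequenced strains colonizes a host
grown in a gnotobiotic system; total RNA is sequenced from two compartments
— colonized roots and the unplanted substrate ("matrix") — with a few
replicates each. Reads are assigned against the pooled coding-sequence
catalog of all strain genomes plus the host.

Two features of this design drive the whole package:

* **Exact duplicates.** Multi-genome catalogs contain byte-identical CDS
  across strains and identical paralogs within strains. Reads cannot
  distinguish members of such a set, so the package works at the level of
  **identity classes** — the partition of the catalog by exact sequence
  equality. Classes are labelled `unique`, `within_strain_paralog`,
  `interstrain_duplicate`, or `mixed` (spanning strains with paralogy inside
  at least one of them).
* **Host dilution.** In root samples a large fraction of reads is
  host-derived; in the matrix essentially none. Strain profiling therefore
  always normalizes within *microbial* reads.

## 2. Read assignment

`build_kmer_index()` indexes every k-mer of every class representative
(k = 31 by default — the standard pseudo-alignment size, comfortably below
the shortest simulated gene; the index refuses k < 11 or k ≥ the shortest
gene). A read's compatibility set is the **intersection over all of its
k-mers** of the classes those k-mers occur in. There is no mismatch
tolerance, skipping heuristic, coverage model, or bias correction: the
contract is exact-k-mer compatibility, which is the right primitive for
error-free reads and keeps the oracle (read-name truth) exact. Orientation
is per read: forward first, reverse complement if the forward orientation
cannot be fully placed.

Ambiguous reads (multi-class compatibility sets) are either discarded
(`unique_only`) or distributed by an EM iteration over equivalence classes,
`c_i <- sum_ec n_ec * w_i / sum_{j in ec} w_j`, weights starting uniform,
stopping when the largest count change falls below `1e-6` or after 100
iterations. Uniquely compatible reads enter the iteration as fixed mass, so
counts are conserved at every step. On duplicate-free catalogs the two
modes coincide (a tested invariant).

## 3. The duplicate rule

Per-strain analyses must not be contaminated by genes that exist
identically in several genomes, while community-scale analyses should not
lose those reads. `resolve_duplicates()` therefore produces two tables from
one set of class counts:

* **per-strain**: classes with scope `interstrain_duplicate` or `mixed`
  removed; within-strain paralog classes kept, counted once under the
  lexicographically smallest member (the representative);
* **community**: every class kept, attributed to its representative.

For **strain relative abundance** the representative attribution is biased:
a low-abundance strain holding the representative of a class shared with an
abundant strain inherits the abundant strain's reads. When the class table
is passed to `strain_relative_abundance()`, counts of interstrain classes
are instead split across member strains proportionally to each strain's
unambiguous read mass in that sample (equally if none) — the attribution an
abundance-aware EM converges to. Gene-level tables are unaffected.

## 4. The differential-expression core

Counts are modelled as negative binomial with `Var = mu + alpha * mu^2`.
The contrast is always root (x = 1) versus matrix (x = 0); positive log2FC
means higher expression in roots.

* **Size factors**: median-of-ratios over genes detected in *all* samples,
  rescaled to geometric mean 1. A strain with fewer than `min_ref_genes`
  (default 10; the threshold is a package choice, exposed as an argument)
  such genes cannot be normalized and is reported *ineligible* rather than
  silently dropped.
* **Dispersion**: per gene, a within-condition method-of-moments estimate
  `alpha_hat = max(alpha_min, (v - m)/m^2)` pooled across conditions with
  df weights. Moments are taken within conditions deliberately: pooling
  across them would absorb the condition effect into the dispersion of
  truly responding genes. A trend `alpha(m) = a0 + a1/m` is fitted by least
  squares over genes with above-floor raw estimates; the final value is the
  weighted geometric mean `raw^(1/3) * trend^(2/3)`, and genes whose raw
  moments difference was non-positive (no usable dispersion information at
  3 replicates) take the trend outright. The weights reflect the
  information imbalance — the raw estimate has two residual df per
  condition — and were chosen for test calibration: with equal weights the
  floored-raw genes collapse the combined dispersion and the Wald test
  becomes anticonservative; the package's Monte-Carlo suite verifies raw
  type-I error within [0.035, 0.065] and empirical FDR of BH calls at or
  below 0.10 under the generator's conditions.
* **Wald test**: the NB GLM `log mu_ij = log s_j + b0 + b1 x_j` is fitted
  with fixed gene dispersion by Fisher scoring (the two-group design makes
  the group log-means orthogonal parameters); the SE comes from the
  observed information and `p = 2(1 - Phi(|b1|/SE))`. Group log-means are
  bounded below at `log(1e-8)`, so a gene with one all-zero condition gets
  a huge but finite fold change with a huge SE (p near 1, shrunken effect
  near 0) instead of infinities. All-zero genes are untested; there is no
  mean-based independent filtering, so the tested universe for enrichment
  stays explicit.
* **Shrinkage**: a normal-prior empirical-Bayes step,
  `shrunk = mle * tau^2/(tau^2 + SE^2)`, with `tau` the upper quartile of
  |log2FC| over well-estimated genes (SE below the median). It has the two
  limits that matter (SE→0 keeps the MLE, SE→∞ shrinks to 0) and never
  increases |log2FC|.
* **Multiplicity**: Benjamini–Hochberg over the tested genes (NAs passed
  through, not counted); DEG means adjusted p < 0.05. An annotation at
  |shrunken log2FC| > 1.5 marks "strong" responders for display, but the
  DEG definition itself is the FDR threshold only.

The per-strain driver runs this pipeline independently per focal strain and
optionally checks user-designated housekeeping genes, which should show no
differential regulation; any that do are flagged.

## 5. Orthogroups and the conserved-response ranking

Orthology is an *input*: a gene → orthogroup map (the package never infers
it from sequence). Aggregation sums member-gene counts per strain exactly;
passing a different grouping (e.g. curated KEGG orthology labels) reruns
the same code path. The community-scale test pools each orthogroup across
all bacterial strains of the *unfiltered* table — interstrain duplicates
included, since no strain attribution is needed there.

The conserved-response statistic is the **cumulative log2FC**: for each
orthogroup the sum of shrunken per-strain log2FCs over the focal strains.
Shrunken (not MLE) values feed the sum so that low-count strains cannot
dominate it; orthogroups absent or untested in a strain contribute 0, which
neither rewards nor penalizes absence (both choices are open in the
problem statement; these are the package's, and the additivity of the
statistic over strain subsets is a tested invariant). Ties break by
community-scale log2FC, then orthogroup id, making the ranking
deterministic. Note that community-scale pooling *attenuates* opposing
responses rather than cancelling them exactly: two strains at +b/−b with
equal abundance pool to `log2((2^b + 2^-b)/2)`, which is 0 only to first
order in b.

## 6. Function

Orthogroups inherit annotation from their best representative member — the
member with the most annotation terms, ties to the longest sequence, then
the smallest gene id (a deterministic stand-in for profile-based
representative selection, which would need external HMM databases).
Enrichment is a classic one-sided Fisher exact test per term against the
tested universe with BH correction (no GO-graph decorrelation; terms with
fewer than 3 annotated universe members are skipped). The
function–abundance regression is OLS of log mean root RA on a category's
mean log2FC across focal strains, with a Pearson correlogram across
categories; COG one-letter classes are treated as the single categorical
scheme for this roll-up.

## 7. Transcriptome structure

Each strain-by-sample transcriptome is one unit: a row of relative
orthogroup counts (summing to 1; all-zero units dropped with a message).
Distances are Bray–Curtis; ordination is classical PCoA (negative
eigenvalues are reported, not corrected; a fully degenerate configuration
returns the origin). PERMANOVA is implemented directly — Gower-centred
inner-product decomposition, *sequential* (type-I) sums of squares in
user-given term order, pseudo-F per term, and
`p = (1 + #{F_perm >= F_obs})/(1 + n_perm)` under free permutation of unit
labels, so p never reaches 0 and the seed fixes the permutations. The SS
type and permutation scheme are genuinely open choices in this setting;
sequential SS with exposed term order (default compartment before
taxonomy) and free permutations are the package's, and an exhaustive
enumeration mode provides exact p on tiny designs. An established
implementation (vegan's) serves as an independent cross-check in the test
suite, never as the computation.

## 8. The synthetic-community generator

The generator is first-class, tested code: it defines the study conditions
under which every claim is verified.

* **Design**: 3 root + 3 matrix replicates by default; per-strain relative
  abundances log-normal (SD 1 on the natural-log scale) drawn
  independently per compartment, so strains genuinely differ between root
  and matrix; within-strain gene expression shares log-normal; counts NB
  with trend `alpha(mu) = 0.05 + 1/mu`; 10\\% of genes truly DE at
  |log2FC| = 2, half up and half down in roots; host genes absorb 51\\% of
  each root sample's reads (and none in the matrix, where the real
  fraction is negligible). The strain-abundance distribution is a modeling
  choice — field data do not pin it down — and is therefore a config
  parameter, not a constant.
* **Catalog**: `n_orthogroups` shared orthogroups with one member per
  strain plus strain-specific singletons; interstrain duplicates created
  by copying a sequence across a random strain pair inside a shared
  orthogroup (each member gene used at most once, so each duplicated gene
  is in exactly one cross-strain class); within-strain paralogs by copying
  between two singleton genes of one strain and merging their orthogroups.
  Fractions are in units of genes involved: `frac * n_strains *
  genes_per_strain / 2` events.
* **Conserved responses**: `n_conserved_ogs` shared orthogroups get
  +`de_log2fc` in a fixed `ceiling(conserved_strain_frac * n_strains)`
  subset of strains, recorded in the truth set for recall tests.
* **Reads**: exactly one error-free, uniform-position substring per count,
  60 bp by default, names encoding the true origin gene. No sequencing
  errors, rRNA, GC bias, or copy-number variation — the assignment
  contract is exact-k-mer compatibility, and those realisms belong to a
  different layer. Consequently, passing tests demonstrate correctness of
  the counting contracts and statistical recovery under the stated model,
  not robustness to base-call errors or bias.
* **Amplicon profile**: multinomial reads around the true compartment
  abundances with a per-strain detection dropout, emulating the lower
  sensitivity of amplicon profiling relative to deep RNA-seq mapping. The
  RNA/DNA abundance comparison defaults to Pearson on log mean abundances
  (the displayed statistic in this field's figures) with Spearman
  available; the pseudo-count is half the smallest nonzero abundance.

Everything is bit-reproducible from `seed`; the four generator stages use
fixed offsets from it.

## 9. Problem sizes and numerical choices

The verification suite measures: duplicate-rule leakage and count
conservation on a 10-strain catalog with 10\\% interstrain duplicates;
assignment L1 error at 10^4 reads/sample; abundance recovery across 20
strains at 10^5 reads/sample; DE calibration, FDR, power, and shrinkage
benefit on 2000-gene, 3+3-replicate simulations; conserved-orthogroup
recall with 20 planted responders among 2000 orthogroups across 20
strains; PERMANOVA type-I error over 1000 null simulations of 12 units
with 999 permutations each; regression recovery at a planted in-sample
R² of 0.5 over 20 strains; and byte-identical pipeline reruns. These sizes
are the package's verification design: large enough for the stated bands,
small enough to run as an ordinary test suite.

Key numerical constants: dispersion floor `alpha_min = 1e-8`; group
log-mean floor `log(1e-8)`; EM tolerance `1e-6` (100 iterations);
Fisher-scoring tolerance `1e-8` (100 iterations, non-converged genes
reported untested); fractional-count detection threshold 1.0 per replicate
(preserving the at-least-one-read meaning under EM's fractional counts).

## 10. Known limitations

* Exact-match assignment only; real reads need trimming/deduplication and
  an error-tolerant quantifier upstream.
* The dispersion/shrinkage estimators are deliberately simple; they
  preserve threshold-level behavior (calibrated p, FDR control, effect
  ranking) but are not numerically interchangeable with heavier
  likelihood machinery.
* Single two-level factor designs only — no batch covariates, interactions
  in the DE model, or outlier refitting.
* Fisher enrichment ignores the GO graph structure.
* PERMANOVA permutes freely; designs needing strata (e.g. repeated
  measures) are out of scope.
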