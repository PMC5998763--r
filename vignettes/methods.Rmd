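---
title: "Matching natural products to human metabolites: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching natural products to human metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Endogenous human metabolites carry curated phenotype associations —
symptoms, diseases, physiological processes they participate in. Natural
products that resemble a metabolite in structure, protein-binding profile
and downstream phenotypic footprint plausibly inherit those associations.
`npmatch` scores that resemblance with three features per compound pair
and lets an ensemble classifier decide which pairs are similar enough for
phenotype transfer.

### Structure

Hashed path fingerprints (bond-order sensitive, hydrogens removed) are
compared with the Tanimoto coefficient. For binary bit vectors the
general form

$$S_{A,B} = \frac{\sum_j x_{jA} x_{jB}}{\sum_j x_{jA}^2 + \sum_j x_{jB}^2 - \sum_j x_{jA} x_{jB}}$$

reduces to $|A \cap B| / |A \cup B|$ over set-bit positions. Fingerprints
are produced by RDKit through a batched subprocess bridge; the exact bit
layout is implementation-defined but deterministic and
canonicalization-invariant (two SMILES spellings of the same molecule
yield identical bits, which the tests assert). Two caveats: RDKit's path
fingerprint ignores chiral tags, so the stereo sensitivity of the CDK
settings the method family historically used is only approximated; and
two all-zero fingerprints give a 0/0 ratio, defined here as similarity 0
because a structureless match carries no evidence.

### Target

For every (target of A, target of B) protein pair, a Smith–Waterman local
alignment under BLOSUM-62 is normalized by the geometric mean of the
self-alignment scores, $SW(a,b)/\sqrt{SW(a,a)\,SW(b,b)}$, giving a
similarity in (0, 1] that is exactly 1 for self-comparison. Gap penalties
are not dictated by the method description; the defaults are the standard
BLOSUM-62 companions gap open 10, gap extend 0.5, both configurable. The
whole sequence is aligned, not the active domain — the intent is shared
biological function, not shared binding pocket.

Within one feature-matrix run, all target-pair scores are pooled and a
single global threshold at the upper 5% tail is computed; a pair's target
similarity is the mean of its scores at or above the threshold (boundary
inclusive). An empty surviving set gives 0 — evidence of dissimilar
target sets — which is deliberately distinct from a missing value (no
scorable target at all). The quantile uses the type-6 plotting position
$h = (n+1)p$ (linear interpolation of the empirical distribution
function) rather than R's type-7 default: with a massed lower mode and a
lone upper outlier, type 7 can return the mode itself, which together
with the inclusive boundary would make the top-5% filter vacuous; type 6
separates the outlier, matching the filter's intent.

### Phenotype

Each compound's targets seed a random walk with restart on the directed
gene/phenotype association network:

$$p_{s+1} = (1 - r)\,M^\top p_s + r\,p_0, \qquad r = 0.7,$$

with $p_0$ uniform over the seed genes and $M$ the out-edge
row-normalized transition matrix. Iteration stops when
$\lVert p_{s+1} - p_s \rVert_\infty < 10^{-5}$. Dangling nodes (no
out-edges — e.g. terminal phenotype nodes) redistribute their mass to the
seed vector; this teleport keeps the operator column-stochastic, so
$\sum_i p_i = 1$ at every step, which the convergence criterion
implicitly assumes. The phenotype profile is the steady-state vector
restricted to phenotype nodes, and the pair feature is the absolute
Pearson correlation of the two profiles. A zero-variance (flat) profile
makes the correlation undefined; such profiles are uninformative and the
similarity is defined as 0 (logged). The iterative solution is checked
against the closed form $p = r\,(I - (1-r)T)^{-1} p_0$ in the tests.

## The pairing model

No gold standard of similar natural-product/metabolite pairs exists, so
the classifier trains on a silver standard: drugs derived from or
designed to mimic human metabolites, paired with those metabolites, are
positives; all other drug–metabolite pairs are unlabeled. Each of 100
ensemble members receives all positives plus a fresh uniform sample of
unlabeled pairs of equal size. Members are RBF-kernel SVMs; several
choices here were genuinely open and are resolved as follows:

* **Kernel and hyperparameters** (unstated upstream): RBF with $C = 1$;
  the kernel width follows the median heuristic (inverse median squared
  pairwise distance of the member's training rows), all exposed in
  `training_config()`.
* **Solver**: no SVM library exists in the supported dependency set, so
  the dual is solved in-package by sequential minimal optimization with a
  deterministic second-choice heuristic (no random working-set
  tie-breaks), and probabilities come from a Platt sigmoid fitted on the
  training decision values by regularized Newton iteration. Training sets
  here are tens to hundreds of rows with three features, where a pure-R
  solver is entirely adequate; determinism buys byte-level
  reproducibility of the whole pipeline.
* **Standardization and imputation**: features are standardized to zero
  mean/unit variance per member, fitted on that member's training rows
  only; missing feature values are imputed with the member's training-set
  median per feature (robust with three features; the upstream method is
  silent on missingness).
* **Aggregation** (unstated): the ensemble score is the arithmetic mean
  of member probabilities, thresholded at 0.5; a majority-vote aggregate
  is available behind `aggregate = "vote"`. The mean was chosen because a
  smooth score is needed for AUROC-based evaluation.
* **Role of cross-validation** (unstated): reporting only. Members are
  fitted on their full training set; per-member 10-fold CV AUROC is
  recorded when `record_cv = TRUE` (off by default — it multiplies
  training cost by the fold count and influences nothing downstream).
  Fold AUROCs are averaged per fold rather than pooled across folds;
  pooling mixes fold-specific probability offsets and fabricates ranking
  signal, which is visible on a constant-feature null.

Phenotype transfer then assigns every term of every predicted-similar
metabolite to the partnered natural product, deduplicated per product
with contributing metabolites accumulated. Transfer can only copy terms
that exist in some source metabolite's annotation — the tests assert it
never invents one.

## Evaluation battery

* **AUROC** uses the rank-sum formulation with midranks for ties — exactly
  the probability a random positive outranks a random negative, ties
  counting one half.
* **Ablation** retrains the ensemble on each feature subset and evaluates
  on held-out positives plus negatives drawn either at random (matching
  the positive count) or restricted to structurally similar pairs. The
  structure floor is strictly `> 0.77` (the upstream description is
  inconsistent between "greater than" and "at least"; strict is
  implemented, the floor is configurable).
* **Indication precision/recall** compares transferred terms against
  known indications after identical normalization on both sides
  (lowercase, punctuation stripped, whitespace collapsed; no ontology
  expansion — anything richer would be unverifiable). The per-pair
  definition is primary — precision over predicted (drug, term) pairs,
  recall over true pairs — with the per-drug "at least one indication"
  variant also reported, since the upstream denominators are ambiguous.
  The random baseline recomputes the transfer over uniformly random
  product–metabolite pairings of the same cardinality.
* **Literature statistics**: for co-occurrence records $(n_c, n_a, n_b,
  N)$, the Jaccard index $n_c/(n_a + n_b - n_c)$ (0/0 defined as 0) and
  the two-sided Fisher exact p-value on
  $[[n_c, n_a - n_c], [n_b - n_c, N - n_a - n_b + n_c]]$, summing
  hypergeometric probabilities no larger than the observed one (with the
  conventional $1 + 10^{-7}$ relative tolerance). Mann–Whitney U compares
  the method's and the random set's distributions, separately for counts
  and Jaccard indices (which statistic the upstream p-values attach to is
  ambiguous, so both are reported); the exact null distribution is used
  for tie-free samples of at most 20, the tie-corrected normal
  approximation otherwise.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` builds a world whose default scale (60 drugs, 40
metabolites, 40 natural products, 80 genes in 20 homology families, 50
phenotypes in 5 modules, 40 positives) is chosen so that every planted
effect is detectable at conventional 3-sigma tolerances on one CPU in
seconds, while preserving the statistical shape of the real task:

* **Molecules** come from a pool of 10 scaffold groups with 4 variants
  each. Within-group Tanimoto averages about 0.6 (some pairs exceed the
  0.77 floor; identical assignments give 1.0), between groups about 0.1.
  Background compounds draw scaffolds uniformly, so structurally similar
  *negative* pairs exist — required by the structure-filtered test mode.
* **Proteins** are mutated copies of family ancestors (per-site
  substitution rate 0.05, lengths 80–200), giving a tunable
  normalized-SW signal without real proteomes.
* **Network** wiring is modular: each gene family feeds one phenotype
  module, plus random extra edges at `edge_density`. Phenotype nodes have
  no out-edges, exercising the dangling-node teleport.
* **Planting**: each feature's `signal_shift` maps to the probability
  (`min(1, shift/3)`) that a positive pair is planted on that feature —
  shared scaffold for structure, targets from the metabolite's homology
  family for target similarity, targets wired to the same phenotype
  module for phenotype similarity. At the default shift of 3 every
  positive is planted; at 0 positives are drawn exactly like background.
  One honesty note: target planting necessarily boosts the phenotype
  feature too (same family implies same module); the reverse is
  decoupled via same-module-different-family targets. The ablation
  acceptance test (structure off, target/phenotype on) is unaffected.
* **Annotations and indications** close the loop: metabolite terms come
  from their targets' phenotype module (plus one noise term), and the
  planted metabolite-like natural products carry indications sampled from
  their paired metabolite's terms plus noise — so indication
  precision/recall has real signal to find.
* **Co-occurrence records** come from two binomial regimes — associated
  ($n_c \sim \mathrm{Bin}(\min(n_a, n_b), 0.2)$) and independent
  ($n_c \sim \mathrm{Bin}(n_b, n_a/N)$) — giving the Fisher/Mann–Whitney
  machinery a known ground truth.

The generator makes no attempt to mimic real chemical-space
distributions, real network topology, term vocabularies or literature
count magnitudes. A green planted-signal test therefore establishes that
the pipeline recovers signal of the planted kind at the planted strength —
not that the method's published corpus-level numbers are reproduced.
Those numbers (headline AUROCs, precision/recall, co-occurrence means)
depend on proprietary and versioned external databases and are out of
scope by design.

## Numerical choices and degenerate inputs

* Random-walk convergence is measured in max-norm; the returned vector
  sums to 1 within $10\times$ the tolerance; non-convergence at the
  iteration cap is an error reporting the final residual.
* Normalized SW is clamped at 1 as a guard against substitution matrices
  without dominant diagonals; with BLOSUM-62 the clamp is inactive.
* A compound with no parseable structure, no scorable target, or no
  target gene in the network carries a missing value in the respective
  feature — distinct from a measured 0 — and nothing is imputed before
  model training.
* All identifiers are whitespace-stripped and compared case-sensitively;
  silent merges are worse than duplicate ids.
* All randomness flows through explicit integer seeds (`withr::with_seed`
  internally), making fixture generation, training-set sampling and the
  random baselines byte-reproducible.

## Known limitations

* Fingerprint stereo sensitivity is approximate (see above).
* Calling RDKit through a subprocess makes structure parsing a batch
  operation; per-call latency is amortized by session-level memoization,
  but an R-native fingerprint backend would be preferable if one were
  available in the dependency set.
* The pure-R SMO solver is not built for large training sets; at the
  silver-standard scale of a few hundred positives it is comfortable, but
  a universe with tens of thousands of positives would warrant a compiled
  solver.
* The per-drug precision/recall variant treats a drug with any correct
  predicted term as a hit; with very permissive thresholds it saturates,
  so the per-pair variant should be read first.
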