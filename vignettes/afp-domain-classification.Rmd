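---
title: "Identifying antifreeze proteins from functional-domain composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying antifreeze proteins from functional-domain composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afpdomains)
```

## The problem and the model

Antifreeze proteins (AFPs) bind ice crystals and depress the freezing
point or inhibit ice recrystallization in organisms from fish to
insects, plants and microbes. AFPs are structurally heterogeneous —
type I/II/III fish AFPs, insect AFPs, antifreeze glycoproteins — so
sequence-composition features generalize poorly across families.
`afpdomains` instead represents each protein by its *functional-domain
composition*: a binary vector over InterPro accessions in which entry
j is 1 iff the protein carries domain j. Domains carry function
directly, including for rare families annotated in only a handful of
proteins.

The engine has four stages:

1. **Encoding.** InterProScan output plus a label list become a sparse
   binary protein × domain matrix. Proteins without any domain
   annotation are removed (their feature vector would be
   uninformatively all-zero) and counted per class.
2. **mRMR ranking.** Domains are ranked greedily by
   *minimum-redundancy-maximum-relevance*. At each step the selected
   domain f maximizes
   $$\mathrm{score}(f) = I(f, c) \;-\; \frac{1}{|S|}\sum_{s \in S} I(f, s),$$
   where c is the class label, S the already-selected set, and
   I(·,·) mutual information. This is the *difference* (MID) variant;
   the redundancy term is zero at the first step, so the ranking
   starts at the single most label-relevant domain.
3. **Incremental feature selection (IFS).** The nested prefixes
   F1 ⊂ F2 ⊂ … ⊂ F_Kmax of the ranked list are each evaluated with a
   random-forest classifier under stratified 10-fold cross-validation.
4. **Model selection.** The optimum prefix is the one with the highest
   Matthews correlation coefficient (MCC); the final forest is trained
   on the full data restricted to those domains.

## Estimators and numerical choices

**Mutual information.** All variables here are binary, so MI is the
discrete plug-in estimate over the 2×2 contingency table,
$\hat I = \sum_{a,b} \hat p(a,b)\log_2 \frac{\hat p(a,b)}{\hat p(a)\hat p(b)}$
in bits, with 0·log(0) = 0. Inside the ranker, the table counts come
from sparse column sums and column–column intersections, so ranking
`top_n` of N domains costs O(N · top_n) MI evaluations rather than the
full quadratic pass. The log base affects no selection decision.

**Tie-breaking.** mRMR scores equal within 1e-9 are treated as tied
and resolved by lowest original column index. A tolerance rather than
exact float equality is used deliberately: two mathematically
identical scores computed by different summation orders can differ at
the 1e-17 level, and a deterministic, reproducible ranking must not
depend on that noise. Column order itself is first-appearance order
(deterministic), never lexicographic. Near-zero MI values are subject
to catastrophic cancellation, so internal consistency checks compare
MI absolutely (to 1e-12), not relatively.

**Classifier.** The random forest uses B = 100 trees, bootstrap
samples of size n drawn with replacement, and ⌊log₂ m⌋ + 1 candidate
features per node for m features (capped to [1, m]). These are the
standard defaults of the classic RF configuration; all are
overridable through `classifier_spec()`. Prediction is majority vote
over the B trees; an exact vote tie goes to the *negative* class —
with a ~4.5% positive class, the conservative call. The fit is
delegated to the `ranger` engine as a probability forest (single
thread, seeded), which makes the vote fraction explicit so the tie
rule is enforced in our code.

**Cross-validation.** Folds are stratified by default: each class is
shuffled separately and dealt round-robin, with the dealing sequence
continued across classes so fold sizes stay within one sample of
equal (at n = k this reduces to leave-one-out). Stratification
matters at this class imbalance — unstratified 10-fold CV can produce
folds with no positive at all, leaving sensitivity undefined. The
fold assignment is a function of the label vector and the seed only,
and the same partition is reused for every subset size, so the IFS
curve reflects feature-set changes, not fold noise. The forest itself
consumes row order through bootstrap resampling, so bit-exact curve
invariance under row permutation is not promised; the tests check
fold-composition invariance exactly and curve agreement statistically.

**Metrics.** SN, SP, ACC and MCC are computed from confusion counts
*pooled* across the k test folds, then the formulas applied once;
per-fold averaging is available via `pooling = "average"` but is not
the default (pooling keeps every measure defined even when a single
fold happens to contain few positives). Any measure with a zero
denominator is defined as 0 and flagged; this keeps IFS comparisons
total, and an all-negative classifier scores MCC 0, not NA. MCC is
the selection measure because it stays honest under imbalance — ACC
reaches 0.955 here by predicting "non-AFP" always. Ties in the curve
maximum resolve to the smallest k (parsimony).

**Seeding.** Every stochastic component — fold assignment, bootstrap,
feature subsampling — draws from sub-seeds expanded deterministically
from one master seed, and seed scopes are local (the caller's RNG
state is untouched).

**Class imbalance** is left untreated by default (no resampling or
class weights): the method's operating point is the raw imbalanced
problem, and MCC-based selection already accounts for it.

## What the synthetic generator emulates

`synthetic_spec()` defines a class-conditional independent-Bernoulli
model with planted structure: `d_inf` informative domains present
with probability `p_pos` (default 0.6) in AFPs and `p_neg` (0.02) in
non-AFPs; `d_red` redundant domains that copy an informative source
and flip each entry with probability 0.05; and `d_noise`
label-independent noise domains at presence rate 0.03. The defaults —
200 positives, 4000 negatives, 10 + 20 + 1000 domains — reproduce the
shape that matters for this engine: a very sparse binary matrix with
~4.5% positives, a small core of genuinely predictive domains,
correlated near-copies of them, and a large irrelevant majority. The
sample count is roughly a quarter, and the domain count a thirteenth,
of a genome-scale annotation set; sizes were fixed once as a
realistic desk-scale testbed for the generator's role (planted-truth
recovery), and the package's statistical tests run at exactly these
conditions.

All-zero rows are *resampled*, not removed, so class counts stay
exactly `n_pos`/`n_neg` and tests can treat the spec as authoritative;
a spec whose probabilities make nonzero rows impossible errors after
bounded attempts.

What the generator does **not** emulate: real domain co-occurrence
network structure (domains travel in architectures), phylogenetic
correlation between proteins, per-family annotation depth, or
duplicate/near-duplicate sequences. Passing the planted-truth tests
therefore shows the engine recovers class-informative, non-redundant
features under an idealized independence model — it does not certify
performance on any real proteome.

## Interpreting an IFS run

```r
gen <- generate_matrix(synthetic_spec(seed = 1))
rk  <- mrmr_rank(gen$matrix, top_n = 30)
res <- ifs_search(gen$matrix, rk, K_max = 30,
                  cspec = classifier_spec(seed = 2),
                  vspec = cv_spec(seed = 3))
res$curve      # k, SN, SP, ACC, MCC for k = 1..30
res$optimum_k  # peak-MCC prefix length
```

The curve typically rises steeply while genuinely informative domains
enter, then flattens or sags as redundant and noise domains dilute
the feature space. On real annotation data the search depth
`K_max = 500` (the package default, matching `top_n`) is ample: the
informative core of a domain-incidence problem is tens of features,
and the published operating point this engine targets peaks near
k ≈ 39 with MCC ≈ 0.94.

## Design choices that were genuinely open

* **mRMR variant:** MID (difference), because the redundancy penalty
  is described as being *subtracted* from relevance; the quotient
  variant (MIQ) is out of scope.
* **Redundancy aggregation:** arithmetic mean of MI with the selected
  set, the standard mRMR form.
* **Pooled vs averaged CV measures:** the reference results are
  reported as single SN/SP/ACC/MCC values over a 10-fold run; pooling
  is the default here (and the only mode in which the zero-denominator
  convention almost never triggers), with fold-averaging exposed for
  sensitivity analysis.
* **Unranked features:** `top_n` defaults to 500 rather than a
  full-length ranking — IFS never looks past its search depth, and a
  full ranking of a 13k-column matrix costs quadratic time for no
  downstream benefit; `top_n = ncol` is available.
* **Proteins labelled but never annotated** are treated exactly like
  annotated-but-empty ones: removed and counted. The removal filter
  is the only sample filter implemented.

## Problem sizes used by the test suite

The packaged statistical tests run the generator at its defaults
(4,200 × 1,030) for ranking recovery and end-to-end IFS (10 seeds,
K_max = 15, which covers the planted core of 10 informative domains),
and at a shape-preserving quarter scale (1,050 × 230) for the
20-seed label-permutation null with the full K_max = 50 search depth.
The scaled null check is the *harder* one — the null MCC distribution
only tightens as n grows — to the point of probing MCC's resolution
limit: with ~48 test positives, pooled counts make the statistic
strongly quantized (a single chance true positive scores ≈ 0.14, two
score ≈ 0.20), so maxima over 50 nested prefixes can brush those
quanta even though no signal is present. A complementary full-scale
permutation test at a fixed subset size (where the null quantum is
≈ 0.07) verifies that shuffled labels leave the cross-validated MCC
at noise level under the default study conditions. The
oracle-equivalence tests
(brute-force greedy mRMR, direct-formula metrics, contingency-table
MI) run at small n where exhaustive re-implementation is exact.

## Known limitations

* The encoding is presence/absence only; domain copy number and order
  (architecture) are discarded.
* Plug-in MI is biased upward at small n; with ~9k samples and binary
  variables the bias is negligible for ranking, but rankings computed
  on very small matrices should be read with care.
* The IFS optimum is a point estimate from one CV partition; on real
  data the peak's location can move by a few k between seeds even
  when the peak MCC barely changes.
* A protein whose true domains are simply unannotated is removed (or,
  at prediction time, all-zero and classified by the forest's
  behaviour on the zero vector); the method cannot rescue missing
  annotation.
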