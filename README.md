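# afpdomains

Identify antifreeze proteins (AFPs) from their functional-domain
composition.

AFPs let fish, insects, plants and microbes survive sub-zero
temperatures by binding ice crystals, but they are structurally so
heterogeneous that sequence-composition predictors generalize poorly
across AFP families. `afpdomains` instead encodes every protein as a
binary vector over InterPro domain accessions — entry *j* is 1 iff the
protein carries domain *j* — and treats AFP identification as feature
selection plus classification on that sparse matrix. It is aimed at
computational biologists who have InterProScan annotations for a
labelled protein set and want (a) a ranked list of the domains that
discriminate AFPs and (b) a compact, well-calibrated classifier built
on them.

## Method

Given the binary protein × domain matrix with class labels
(1 = AFP, 2 = non-AFP):

1. **mRMR ranking** (difference variant). Features are selected
   greedily; at each step the chosen domain *f* maximizes

   score(f) = I(f, c) − (1/|S|) Σ_{s∈S} I(f, s)

   where *c* is the class label, *S* the already-selected set, and
   I(·,·) the discrete plug-in mutual information in bits (for binary
   variables, a 2×2 contingency-table sum). Relevance to the class is
   rewarded, average redundancy with what is already selected is
   penalized; ties break to the lowest column index.

2. **Incremental feature selection (IFS).** The nested prefixes
   F₁ ⊂ F₂ ⊂ … ⊂ F_Kmax of the ranked list are each evaluated with a
   random forest (B = 100 trees, ⌊log₂ m⌋+1 candidate features per
   node, bootstrap size n) under stratified 10-fold cross-validation.
   Confusion counts are pooled over folds and summarized as
   sensitivity SN = TP/(TP+FN), specificity SP = TN/(TN+FP), accuracy
   ACC, and the Matthews correlation coefficient

   MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)).

3. **Model selection.** The optimum prefix maximizes MCC (smallest k
   on ties) — MCC rather than ACC because at ~4.5% positives an
   all-negative classifier already reaches ACC ≈ 0.955. The final
   forest is trained on the optimum domains; vote ties at prediction
   time go to the negative class.

A synthetic-matrix generator with planted informative, redundant and
noise domains (`synthetic_spec()` / `generate_matrix()`) makes the
whole pipeline testable without any downloads.

## Worked example

```r
library(afpdomains)

gen <- generate_matrix(synthetic_spec(seed = 1))  # 200 AFP + 4000 non-AFP
print(gen$matrix)
#> DomainMatrix: 4200 proteins x 1030 domains
#>   positives (AFP): 200 | negatives: 4000 | density: 0.0314

rk <- mrmr_rank(gen$matrix, top_n = 30)
head(as.data.frame(rk), 3)
#>   rank index   domain      score  relevance redundancy
#> 1    1     2 DINF0002 0.11340660 0.11340660 0.00000000
#> 2    2     7 DINF0007 0.05933957 0.10084828 0.04150872
#> 3    3     9 DINF0009 0.05571992 0.09606525 0.04034533

res <- ifs_search(gen$matrix, rk, K_max = 30,
                  cspec = classifier_spec(seed = 2),
                  vspec = cv_spec(seed = 3))
print(res)
#> IFS over k = 1..30 (10-fold CV, 100 trees)
#> optimum k = 19
#> SN = 0.9600  SP = 0.9998  ACC = 0.9979  MCC = 0.9761
```

The ranking puts the planted informative domains (`DINF*`) first —
their `relevance` column is the MI with the class label and the
`redundancy` column is the average MI with the domains ranked above
them. The IFS curve climbs steeply while informative domains enter
(MCC 0.63 at k = 1, 0.93 at k = 5, 0.97 at k = 10) and flattens once
the planted core of 10 is in; the peak of this run's curve selects 19
domains with cross-validated sensitivity 0.960, specificity 0.9998 and
MCC 0.9761. `train_final()` then fits the deployable forest on those
domains, and `predict()` / `save_model()` / `load_model()` apply and
persist it.

Real data enter through `parse_annotations()` (InterProScan TSV or a
2-column `protein<TAB>domain` file), `read_labels()` and
`build_domain_matrix()`, or a prebuilt sparse matrix via
`read_domain_matrix()` (triplet TSV or MatrixMarket + sidecars).

The same pipeline is scriptable from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/afpdomains.R", package="afpdomains"))')" \
  all --annotations ann.tsv --labels labels.tsv --out-dir run1 --seed 7
```

with commands `encode | rank | ifs | train | predict | simulate | all`,
YAML config support, and a reproducibility manifest per run.

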