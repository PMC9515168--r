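---
title: "Pathway-based transfer learning for drug-response prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-based transfer learning for drug-response prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Large in-vitro screens measure drug sensitivity on tens of thousands of
(cell line, drug) pairs, while clinical tumor and patient-derived xenograft
(PDX) cohorts are tiny — often well under a hundred treated samples per
outcome type. `pathdrp` implements a transfer-learning workflow for this
asymmetry: a feed-forward sensitivity network is pre-trained on the large
cell-line panel, and its layers are transferred into a classifier or
regressor that is fine-tuned on the small target cohort. Features are
deliberately pathway-level rather than gene-level, which both regularizes
the transfer (pathways are more stable across domains than single genes)
and makes the predictions explainable in biological terms.

## Feature construction

Every (sample, drug) instance is the concatenation `EXP ‖ CHEM ‖ DGNet`:

* **EXP** — per-sample pathway activity from single-sample gene-set
  enrichment (ssGSEA). Genes are ranked within each sample by descending
  harmonized expression; the running sum gains
  $w_i = |r_i|^\alpha / \sum_{j \in S} |r_j|^\alpha$ at in-set genes
  (with $r_i$ the normalized rank) and loses $1/(N - |S|)$ at out-of-set
  genes; the score is the integral (sum) of the running sum. The exponent
  defaults to $\alpha = 0.25$ with rank-normalized weighting, the canonical
  single-sample formulation; `score = "max"` gives the classic GSEA
  max-deviation statistic for comparison. At $\alpha = 0$ the score depends
  on expression only through ranks. Pathways overlapping the measured genes
  by fewer than 5 members (`min_overlap`) are dropped, a standard GSEA
  practice. Permutation p-values (`permutation_significance`, 1000
  permutations by default) resample gene membership at fixed set size;
  they are descriptive and the raw scores are used as features.
* **CHEM** — a 256-bit folded circular fingerprint of the drug's SMILES.
  Heavy-atom graphs are parsed with ChemmineR/OpenBabel; atom environments
  are hashed iteratively (element, degree, summed bond orders, then
  neighborhoods out to `radius = 2`, the ECFP4-equivalent default) and all
  identifiers are folded modulo 256.
* **DGNet** — the network-propagated influence of the drug's protein
  targets on each pathway. The targets seed a random walk with restart
  ($p = r e + (1-r) W p$, column-normalized weighted adjacency, restart
  probability 0.5, power iteration to an L1 tolerance of 1e-8; dangling
  columns teleport to the restart distribution so the stationary vector is
  an exact probability distribution). A pathway's raw score is the mean
  stationary probability over its member genes, and the feature is its
  z-score against a null of uniformly drawn equal-size target sets
  (`n_perm` per drug; a degree-matched null is available via
  `null = "degree_matched"`). Drugs with no targets in the graph keep an
  all-zero, flagged DGNet block rather than being dropped — real drug
  panels contain compounds with unknown targets.

## Expression harmonization

Source and target expression matrices are harmonized in three steps:
restriction to the common gene set; gene-wise standardization of the pooled
matrix to mean 0 / SD 1 (sample SD, $n-1$); and empirical-Bayes
location/scale batch adjustment in the Johnson (ComBat) parametric form.
Per batch $b$ and gene $g$, the raw additive effect $\hat\gamma_{bg}$
(batch mean) gets a normal prior and the multiplicative effect
$\hat\delta_{bg}$ (batch variance) an inverse-gamma prior, with
method-of-moments hyperparameters across genes; the conditional posterior
estimates are iterated to a tolerance of 1e-4 and the adjusted value is
$(z - \gamma^*_{bg}) / \sqrt{\delta^*_{bg}}$. Because standardization is
pooled, the grand mean is zero and no re-centering term remains. Design
choices: standardization happens once on the pooled matrix before the EB
step (the three-step reading of the procedure); covariates such as cancer
type are not part of the batch model; non-parametric and reference-batch
variants are out of scope. `sva::ComBat` is used in the test suite as an
independent cross-check of the adjustment, never as the implementation.

Note one numerical reality checked by the tests: EB shrinkage leaves
per-batch residuals of order $1/\sqrt{n}$, so re-running harmonization on
its own output moves values by that order (not by machine precision), and
single extreme entries can move by a few times the mean adjustment error.

## The sensitivity network

A feed-forward network with ELU hidden activations (production-scale
widths 1000–800–500–100; tests and the bundled synthetic studies use
64–32–16–8), a linear output for regression and a sigmoid for
classification. Training uses Adamax at learning rate 4e-4, neuron dropout
0.10, RMSE loss for pre-training (MSE/BCE for fine-tuning), weight values
clipped into $[-5, 5]$ after every gradient update (read as weight, not
gradient, clipping), and early stopping with patience 30 on a held-out
validation split with best-epoch restoration. Initialization is a seeded
uniform fan-in scheme; every source of randomness (init, splits, shuffling,
dropout) derives from the configuration seed, so training is bit-for-bit
reproducible on CPU.

Validation-split conventions: 10% of the training data (stratified by
drug) during pre-training on large panels; 20% during fine-tuning. The
target cohorts are small enough that early stopping on a ~30-row split was
visibly erratic; doubling the split stabilized it at negligible cost.

Pre-training targets the continuous sensitivity (a 1-AUC-style outcome in
[0, 1], higher = more sensitive); a potency-style `neg_log10_ic50` target
is supported for model-selection comparisons, with losses living on their
own response scales.

## Transfer and fine-tuning

`transfer_build` copies the first $k \in \{0..4\}$ hidden layers from the
pre-trained model (frozen or retrainable), optionally appends new hidden
layers, and attaches a fresh task head. `fine_tune` then trains under the
same clipping/early-stopping contract; frozen layers are bitwise untouched.
When transferred layers are retrainable, a **head warmup** phase first
trains the new layers alone (30 epochs, learning rate 2e-3, transferred
layers held fixed) before joint training: a randomly initialized head
otherwise back-propagates noise through — and can permanently scramble —
the transferred representation on small, noisy cohorts.

Class imbalance is handled by per-drug undersampling: all responders are
kept and non-responders are drawn without replacement down to a 1:3
responder:non-responder ratio (or all of them, if fewer), with
zero-responder drugs dropped.

Hyperparameter search (`hyperparameter_search`) is sequential model-based
optimization: a Gaussian-process surrogate (RBF kernel on the unit-cube
encoded space, fixed length-scale 0.3, standardized objective) maximizing
expected improvement over randomly proposed candidates, with the objective
defaulting to the mean metric of an inner 3-fold split of the training data
(nested, to avoid test leakage). Any sequential optimizer satisfying the
planted-optimum recovery test would do; the GP-EI choice is the field's
default.

## Evaluation

Five-fold cross-validation repeated five times (25 fold scores), stratified
by (drug, label) for classification; AUROC is the Mann–Whitney
probability-of-concordance form with ties counted one half, RMSE the usual
root mean squared error. Arms are compared with the Mann–Whitney U test on
fold scores (exact for ≤ 8 per side without ties, normal approximation with
tie correction otherwise). Per-drug and per-cancer breakdowns use pooled
out-of-fold predictions (averaged across repeats) rather than per-fold
metrics — small groups make per-fold AUROC undefined — and exclude groups
with fewer than 5 rows or a single class; means are reported separately
for groups present and absent in the source panel.

## Explanation

Feature attributions are Shapley values: exact subset enumeration for ≤ 12
features, otherwise a permutation-sampling estimator in which each sampled
permutation is combined with every baseline row in turn. This makes the
efficiency identity — attributions sum to $f(x)$ minus the mean baseline
prediction — hold exactly rather than in expectation; linearity, symmetry
and dummy axioms are asserted directly in the tests. Importance is the
mean absolute Shapley value across samples, ranked per drug when the
per-drug analysis is requested. Responders and non-responders are defined
as true positives and true negatives of the classifier (threshold 0.5,
probability exactly at threshold counted positive), and per-pathway
enrichment (the ssGSEA scores, not the attributions — the procedure's
ambiguity is resolved in favor of enrichment) is compared between the two
groups with two-sided Mann–Whitney tests and Benjamini–Hochberg adjustment
at FDR 0.05.

## The synthetic cohort generator

`generate_cohort` emulates exactly the statistical structure the method
assumes, with known ground truth:

* pathways are overlapping blocks over the gene universe; each sample has
  latent activity $a_p \sim N(0,1)$ per pathway; member-gene expression is
  baseline + summed activities + $N(0, \sigma)$ noise;
* batch effects are gene-wise location/scale distortions
  (shift $\sim N(0, \text{shift\_sd})$, scale $\sim U(\text{range})$)
  applied to the varying part of expression — precisely the family the EB
  adjustment models, so harmonization can in principle remove them;
* the PPI graph is dense within pathways, sparse across, with a weak ring
  for connectivity; drug targets are drawn from each drug's signal
  pathways, making DGNet informative by construction;
* continuous response is a logistic link over the signed signal-pathway
  activities plus a drug intercept, plus $N(0, \sigma)$ noise, clipped to
  [0, 1]; dichotomous labels are the per-drug median split (strictly
  greater-than); cells and tumors share one generative law so that transfer
  is beneficial, with tumor cohorts small by design;
* synthetic drugs get simple, chemically valid SMILES (unique
  carbon-chain variants) so fingerprinting exercises a real parser.

One seed fixes the entire cohort bit-for-bit. What the generator does *not*
emulate: real marginal expression distributions, dose-response curve
fitting (sensitivity is generated directly), gene-gene correlation beyond
pathway co-membership, and covariate-confounded batch structure. Passing
tests on these cohorts therefore demonstrate correctness of the machinery
and recoverability of planted signal under the model's own assumptions —
not clinical performance.

## Study problem sizes

The bundled experiments (`study_cohort`, `transfer_benefit_experiment`,
`signal_recovery_experiment`, `run_demo`) use 200 genes / 20 pathways,
2000 cell samples, 80 tumor samples, 5 drugs, effect size 1.5 and noise SD
0.5, with network widths 64–32–16–8; the demo halves the cell panel.
These sizes keep a full run in the minutes range on one CPU while leaving
the transfer benefit, harmonization recovery and pathway-recovery effects
comfortably measurable. Pre-training on these cohorts uses learning rate
1e-3 and up to 60 epochs: the panels are two orders of magnitude smaller
than a production screen and the production default of 4e-4 underfits
within that budget; fine-tuning keeps 4e-4.

## Known limitations

* DGNet's upstream formulation (restart probability, null, normalization)
  lives in the original method's prior work; our defaults (0.5, uniform
  null, z-score) are explicit configuration, not a claim about the
  original.
* Whether the original workflow used raw or normalized enrichment scores
  as features is ambiguous; we default to raw and expose `normalize`.
* The hyperparameter search space defaults are sensible, not a
  reproduction of any published table.
* The harmonization standardizes the pooled matrix once; a per-dataset
  standardization variant would differ in detail.
* Gene identifiers are opaque symbols: no alias resolution or identifier
  remapping is attempted.
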