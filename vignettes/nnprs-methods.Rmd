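---
title: "Neural-network polygenic risk scores: models, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural-network polygenic risk scores: models, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A polygenic risk score (PRS) condenses genotype information into one
number. The simple form is a weighted sum of effect-allele counts,
$s = \sum_i w_i g_i$ with $g_i \in [0,2]$. Clinically important scores --
notably type 1 diabetes and celiac disease scores built around the HLA
region -- add *interaction terms*: contributions keyed to specific genotype
combinations at pairs of SNPs (e.g. the DR3/DR4 heterozygote effect). Those
scores are normally distributed as bespoke code, which is hard to port
across languages and decays as software environments change.

`nnprs` treats PRS generation as a small supervised-learning problem: train
a multilayer perceptron (MLP) on genotype inputs with the programmed PRS as
the label. A trained network is just four matrices, four bias vectors and a
ReLU, so it can be shipped as a plain text file and evaluated anywhere
matrix multiplication exists. Beyond portability, the network route has a
second payoff: when some input SNPs are unavailable, a network trained on
the reduced input can exploit linkage disequilibrium (LD) among the
remaining SNPs to recover part of the lost signal, which a fixed formula
cannot.

## Score representation

`prs_definition()` stores additive weights, an intercept, and interaction
terms in two modes: `product` ($w\,g_a g_b$) and `state_indicator`
($w\,\mathbf{1}\{g_a = s_a \wedge g_b = s_b\}$, $s \in \{0,1,2\}$). The
indicator mode is the natural encoding of HLA-type interactions, which fire
on specific genotype configurations rather than scaling with dosage.
Because imputed dosages are fractional, indicator matching happens after
rounding to the nearest integer -- consistent with the autoencoder's output
head, which is built to predict the values 0, 1, 2.

The published T1D and celiac score weights are not reprinted here; real
weight files can be loaded with `load_prs_definition()`. For self-contained
experiments, `make_template_prs()` draws structural stand-ins with the
published SNP counts (10, 30, 67, 42), one interaction term for the two
small scores and a set of state-indicator terms concentrated on a
designated correlated block (14 SNPs for the 67-SNP template, 10 for the
42-SNP one) for the large ones. Additive weights are drawn uniformly on
[0.05, 0.5] (block SNPs on [0.3, 1.2], as HLA tag SNPs carry the largest
weights) and interaction weights from a centred normal with standard
deviation 1.2, so both risk-raising and protective configurations occur, as
in the real scores.

## The synthetic cohort

The package never requires biobank data. `simulate_template_cohort()`
builds:

* **Genotypes.** Each genotype is the sum of two haplotypes. Per haplotype,
  a latent standard normal vector with equicorrelation $\rho$ inside the
  designated block (identity elsewhere) is thresholded at the
  allele-frequency quantile -- a Gaussian copula. Default $\rho = 0.9$
  emulates a tight LD block of mutually predictable SNPs, the regime in
  which missing-SNP compensation is possible at all. Frequencies are drawn
  uniformly on [0.05, 0.5] (block SNPs [0.2, 0.45]: HLA tag SNPs are
  common variants).
* **Case labels.** $P(\text{case}\mid s) =
  \mathrm{logistic}(\alpha + \beta z)$ with $z$ the standardized score;
  $\alpha$ is solved numerically so the mean probability hits the target
  prevalence (tolerance $10^{-4}$). Defaults $\beta = 2$, prevalence 0.02:
  $\beta = 2$ puts the score's case/population AUC near 0.92, matching the
  discrimination of a strong clinical PRS, and 2% prevalence leaves a few
  hundred cases in a 20,000-sample cohort so AUC estimates are stable.
* **Splits.** All cases are held out as a dedicated case test set; the
  remaining $m$ samples split 70/15/15 with `floor` for training and
  validation and the remainder to test. This rounding convention is the
  unique one consistent with all three published UK-Biobank-scale split
  count triples, which the test suite checks exactly. A sample may belong
  to several case sets (the published design has 8 samples in two).

What the simulator does **not** emulate: LD decay with distance (the block
is equicorrelated), population structure and relatedness, genotyping or
imputation error, and liability-threshold disease architecture. Passing
tests therefore demonstrate the *mechanisms* -- interaction learning, LD
-driven imputation, text-bundle portability -- not performance on any real
cohort.

## Models and training

* **Standard MLP**: hidden layers 50/30/20, ReLU, one linear output
  neuron. The multi-predictor variant widens the output to one neuron per
  score and is otherwise unchanged.
* **Linear predictor**: ordinary least squares, optionally with an
  elastic-net grid ($\lambda_1$, $\lambda_2$ each $\{0\} \cup$ 7 log-spaced
  points in $[10^{-4}, 1]$) selected by validation MSE. The penalized
  objective $\|Xw-y\|^2 + \lambda_1\|w\|_1 + \lambda_2\|w\|_2^2$ is solved
  by glmnet after reparameterization; $\lambda_1=\lambda_2=0$ falls back
  to the exact least-squares solution (minimum-norm with a warning if the
  design is rank-deficient).
* **Autoencoder (AE)**: input = retained SNPs, two ReLU hidden layers as
  wide as the full SNP set, output = the full set through a
  sigmoid-times-two head, so predictions live in (0, 2). Trained against
  the intact SNP vectors. **AE-MLP** feeds the reconstruction to the
  full-SNP-trained MLP.

Training uses minibatch Adam (betas 0.9/0.999, eps 1e-8) on the MSE,
learning rate 1e-4 and batch size 5 for regressors, 5e-5 for the
autoencoder. The stopping rule is a package design decision: validation
loss is evaluated every 2,000 iterations; training stops after 3
evaluations without improvement or 30 epochs, and the best-validation
parameter state is returned (so the returned model is never worse than its
initialization on the validation set). Initialization is He-uniform
($\mathrm{Var}(w) = 2/d_{in}$), seeded. The choice is deliberate: with the
milder $U(\pm 1/\sqrt{d_{in}})$ scheme the forward signal of the 7-layer
catalogue variants vanishes at initialization (output standard deviation
around $10^{-4}$) and those networks collapse to constant predictors,
whereas He scaling preserves activation variance through ReLU stacks of
any depth. Batch shuffling uses its own seeded generator, so training is
bit-reproducible.
Inputs are fed as raw counts in [0, 2] with no standardization -- the scale
is already narrow and homogeneous.

One ambiguity deserves a note: the portable-forward-pass convention applies
the activation at every one of the four steps, while the training
description gives the output neuron no activation. The package uses a
linear output everywhere and records an explicit activation tag per layer
in the export format, so a bundle is self-describing rather than
convention-dependent.

## Missing-SNP experiments

`make_removal_permutation()` draws a seeded removal order (optionally
restricted to the correlated block) with nested retained sets;
`run_subset_experiment()` retrains each method from scratch per subset --
no warm starts, so each subset model is the model a user could train on
demand -- and reports test-split Spearman and RMSE against the *full*-SNP
PRS plus case-versus-population AUC, all with percentile bootstrap CIs.
Bootstrap resamples are shared across methods (and AUC resampling is
stratified by class), so method differences are paired. The reduced-SNP
PRS baseline zeroes removed dosages and drops interaction terms touching a
removed SNP.

A caution learned from the implementation: the reduced-PRS rank
correlation is *not* exactly monotone along a removal permutation when
interaction weights have mixed signs -- removing a SNP whose negative
-weight term distorts the ranking can raise the correlation. Exact
monotonicity holds for purely additive positive-weight scores, and that is
the form in which the property is tested.

`leave_one_out_predictability()` trains one AE per held-out SNP and
reports the Pearson correlation between its prediction and the truth on
the test split; a constant (monomorphic) target is reported as $r = 0$
with a degeneracy flag rather than `NA`.

## Variant catalogue

`make_variant()` fixes the architecture/encoding catalogue used to probe
whether the missing-SNP ceiling is a model limitation: capacity changes
(one 200-neuron layer; 7 layers of 55/50/40/30/25/15/5; 7 layers of
200/160/120/90/70/50/10), an unweighted input skip connection into the
last hidden layer, a pairwise-product input expansion
($p \to p + p(p-1)/2$; 52 SNPs become 1,378 features), and a learning-rate
by batch-size grid (1e-3/1e-4/1e-5 by 5/20/100 -- values the package fixes,
centred on the defaults, since the original grid is unstated).
`run_variant_study()` trains the catalogue on one subset task, reports the
same metric trio with shared resamples, per-variant prediction agreement
with the standard model, and the ensemble mean. The scientific expectation,
which the acceptance test asserts on synthetic data, is a null result: all
CIs overlap, agreement is high, the ensemble does not help -- evidence that
the input information, not the model, is the binding constraint.

## Text export

`export_network()` writes `[SNPS]`, `[OUTPUTS]` and `[LAYER]` sections
with 17-significant-digit decimals (lossless for IEEE doubles, so a
roundtrip is bit-exact), including the ordered SNP list with effect
alleles -- the only side information a recipient needs.
`forward_from_text()` evaluates a bundle with `%*%`, `+` and `pmax` only,
and the test suite additionally checks a bundle against an evaluator
written from scratch against the format description, sharing no package
code: the portability claim as a unit test.

## Problem sizes

The packaged experiments run at desk scale, chosen so the full suite
completes in minutes while leaving the qualitative results stable:
PRS-recreation at $n = 100{,}000$ (67-SNP score) and $n = 50{,}000$
(10-SNP score); the missing-SNP and variant studies at $n = 20{,}000$ with
three evaluated removal steps, four leave-one-out targets and a reduced
2-by-2 hyperparameter grid; unit tests at $n \le 10{,}000$. The
training-set-size sweep mirrors the observation that performance survives
well below 10,000 training samples.

## Known limitations

* The simulator's equicorrelated block is a deliberately simple LD model;
  real HLA haplotype structure is richer, and real missing-SNP recovery
  will depend on it.
* Template interaction terms are structural stand-ins, not the published
  clinical weights; conclusions about *which* SNPs matter do not transfer.
* Each missing-SNP subset requires its own retrained model; the package
  supports training them on demand but ships no pre-trained model zoo.
* Elastic-net support targets the many-samples/few-features regime of PRS
  inputs; it is not a general high-dimensional solver.
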