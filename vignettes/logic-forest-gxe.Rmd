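---
title: "Screening for gene-environment interactions with logic forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for gene-environment interactions with logic forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Case-control studies of complex diseases such as systemic lupus
erythematosus often hypothesize that risk arises from *joint* conditions --
a particular genotype **and** a particular exposure -- rather than from
marginal effects alone.  Exhaustive screening is hopeless: with $p$ binary
predictors there are $2^p - 1$ possible main effects and interactions
(over $10^7$ already at $p = 25$), and regression approaches that enumerate
two-way products miss higher-order terms entirely.

`logicgxe` implements a two-stage analytic strategy for this setting:

1. **Search** with an ensemble of Boolean logic trees ("logic forest"),
   which explores conjunctions of up to eight binary conditions without
   pre-specifying them, and ranks every conjunction it finds by two
   importance measures plus a permutation p-value.
2. **Confirm** the handful of top-ranked conjunctions with ordinary
   univariate logistic regression, reporting odds ratios with confidence
   intervals.

## Data model and encodings

The analysis unit is a binary matrix.  SNP dosages (minor-allele copy
counts 0/1/2) are converted to indicators under one of three genetic
models:

* **recessive** -- 1 iff two copies of the minor allele; the *complement*
  of this indicator reads ">= 1 copy of the major allele", which is how
  complemented recessive literals are rendered in reports;
* **dominant** -- 1 iff at least one copy;
* **genotypic** -- two indicators (exactly one copy; exactly two copies)
  with zero copies as reference.

Binary exposures (e.g. childhood passive smoke, `psc`) and demographics
enter unchanged.  Subjects with any missing genotype, status or selected
exposure are dropped listwise at assembly -- no imputation -- matching how
the motivating cohort was analysed.  Upstream, `apply_qc()` screens
markers by Hardy-Weinberg equilibrium *in controls only* (default
chi-square, p < 0.001 drops the marker; an exact conditional test is
available because the chi-square approximation is poor at small
genotype counts), minor-allele frequency (< 0.05 drops), missingness
(any missing call drops, configurable), and optional +-5 kb gene-region
windows (1-based closed intervals; BED input is converted from its
0-based half-open convention).

## The model

A **logic tree** $T$ is a binary tree whose internal nodes are AND/OR and
whose leaves are literals $x_j$ or $\neg x_j$; a subject is predicted
diseased iff the expression is true.  Written in disjunctive normal form,
$T$ is an OR of conjunctions; the surviving conjunctions (after removing
contradictions, merged duplicates and absorbed supersets) are the tree's
**prime implicants** -- the interpretable "risk conditions" the tree
asserts.

A **logic forest** is a bagged ensemble $\{T_1, \dots, T_B\}$: each tree
is fitted to an independent bootstrap sample (size $n$, with replacement)
of the data, with all $p$ predictors visible to every tree (rows are
resampled, columns are not).  The ensemble predicts by vote share with
ties going to the case class ($\ge 0.5$).  Each tree's out-of-bag (OOB)
set -- the subjects absent from its bootstrap sample -- supports unbiased
error estimation:

* the forest OOB error is the mismatch rate between $y$ and the
  per-subject OOB majority vote (subjects that are OOB in no tree are
  excluded with a warning; at the default $B = 200$ this is vanishingly
  rare);
* the per-tree OOB error is the tree's mismatch rate on its own OOB
  subjects.

Two importance measures are attached to every prime implicant $X_j$ found
anywhere in the forest:

* **VI1 (permutation importance)** -- the average over all $B$ trees of
  the increase in per-tree OOB error after the predictor columns of
  $X_j$ are permuted by *one shared* row permutation.  Permuting jointly
  preserves the implicant's internal joint distribution while severing its
  association with the outcome and the other predictors.  VI1 ranges over
  $[-1, 1]$; a predictor used by no tree scores exactly 0.
* **VI2 (frequency importance)** -- the fraction of trees whose DNF
  contains $X_j$ (canonical-key equality: literal sets compare equal
  regardless of construction order).

Individual predictors get the same treatment, a predictor "occurring" in a
tree when any implicant of that tree uses it, complemented or not.
Reported `normalized_vi1` divides by the table's maximum absolute VI1 --
a plotting convention, not part of inference.

**Permutation p-values** refit the whole forest `n_perm` times (500 by
default) on outcome-permuted data; the p-value for $X_j$ is the
proportion of permuted forests whose importance for $X_j$ meets or
exceeds the observed one, with implicants absent from a permuted forest
contributing importance 0.  The resolution is $1/\texttt{n\_perm}$ and a
zero count is reported as "< 1/n_perm"; a +1-corrected estimator is
available by flag.

## Fitting: simulated annealing

Each tree minimises in-sample misclassification over trees of at most
`max_leaves = 8` leaves.  The search is simulated annealing over the
classical move set -- alternate a leaf's literal (complement toggles
included), alternate an operator, split a leaf, grow a branch, delete a
leaf, prune a branch -- with moves drawn uniformly from the legal subset,
so a single leaf can never become empty and growth stops at the cap.
The start temperature is calibrated from a 100-move pilot walk so that
roughly half of typical worsening moves are accepted; cooling is
geometric over 25,000 iterations (all configurable through
`anneal_control()`) down to ~1% acceptance.  The best state visited is
returned, with score ties resolved toward fewer leaves for parsimony and
determinism.  Scores are compared as integer mismatch *counts*, so there
is no floating-point tie ambiguity, and candidate evaluation packs
subjects into 64-bit words, making a proposal's cost about
$\lceil n/64 \rceil$ word operations per node.  All randomness flows
through R's RNG: a `set.seed()` call makes tree, forest and permutation
results bit-reproducible.

Degenerate inputs are handled explicitly: a constant outcome yields a
warning and the best single-leaf tree; a bootstrap draw with an empty OOB
set (possible only at tiny $n$) is redrawn; constant predictor columns
are retained with a warning at assembly.

## The synthetic-data generator

Because the motivating cohort is not redistributable, `sim_config()` /
`sim_study()` generate studies with the statistical structure the
analysis assumes: independent Hardy-Weinberg genotypes at specified
minor-allele frequencies (optionally block-correlated via latent-Gaussian
thresholding per haplotype, which keeps HWE margins while inducing
approximate genotype correlation); independent binary exposures at
specified prevalences; and outcomes from a logistic model
$\operatorname{logit} P(y=1) = \beta_0 + \sum_k \beta_k I(\text{term}_k)$
whose terms are Boolean conjunctions over the *encoded* predictors, so a
planted gene-environment interaction is expressible exactly as a prime
implicant (e.g. `psc & !snp001_R`, childhood passive smoke together with
at least one major allele).

Defaults mirror the motivating study's shape: 204 subjects, 148 SNPs
(recessive encoding plus the five exposure/demographic columns gives
$p = 153$), exposure prevalences at the pooled cohort values (psc 0.338,
psa 0.186, ever smoker 0.235, current smoker 0.147, female 0.858), MAFs
uniform on [0.1, 0.5] when unspecified, and a baseline log-odds of
`qlogis(0.49)` matching the cohort's case fraction.  The planted-effect
fixture used throughout the tests places `psc & !snp001_R` at odds ratio
2.3 -- the magnitude of the interaction odds ratios the two-stage
analysis is meant to detect -- with the planted SNP's MAF fixed at 0.4 so
that the recessive class (16%) makes the conjunction genuinely distinct
from `psc` alone.

What the generator does *not* emulate: population structure and
admixture, realistic LD decay, genotyping-array site ascertainment, or
gene-environment correlation (exposures are independent of genotypes by
default; a correlation knob exists to stress that assumption).  Passing
tests on synthetic data therefore demonstrate correctness of the
machinery, not robustness to those real-data complications.

## What the package's own experiments show -- and two honest limitations

The test suite verifies the machinery against independent oracles:
DNF-vs-tree equivalence by exhaustive truth-table enumeration, OOB
quantities by naive double-loop recounts, the logistic odds ratio against
the 2x2 cross-product, the ROC area against the rank-sum statistic, and
the chi-square flavors against closed forms.  Two scientific properties,
however, deserve a frank account, because the package's own desk-scale
experiments show them *failing* under conditions one might expect them to
hold:

1. **Weak conjunctions are hard to recover under 0/1 loss.**  With
   `psc & !snp001_R` planted at OR 2.3 ($n = 600$, MAF 0.4), the
   misclassification gain from refining `psc` by the genotype literal is
   about $10^{-3}$ -- under one subject in 600 -- while bootstrap
   resampling perturbs scores by an order of magnitude more.  Eight-leaf
   trees therefore decorate `psc` with interchangeable high-prevalence
   complement literals, and the exact planted implicant frequently appears
   in no tree at all.  The forest reliably detects *that* `psc` matters
   (it tops the predictor table), but exact-identity recovery of a
   moderate-effect conjunction as the top implicant is not a property this
   estimator has at these effect sizes.  Stronger effects (the noiseless
   planted conjunctions in the unit tests) are recovered exactly.

2. **Permutation p-values for data-selected implicants are
   anti-conservative.**  The tested implicant is chosen as the *maximum*
   of the observed importance table, while its null distribution is built
   from permuted forests in which the same implicant -- especially a
   multi-literal one -- rarely reappears and then scores 0.  Under a
   global null, the top implicant's permutation p concentrates near 0
   rather than being uniform.  These p-values are evidence summaries for
   *pre-declared* implicants; for the forest's own top terms they should
   be read as descriptive, which is one reason the workflow ends with a
   logistic confirmation stage rather than with the permutation test.

## Problem sizes used in the checks

The packaged experiments run at desk scale, chosen to exercise every code
path: forests of 10-100 trees on 25-600 subjects; 1,000 random trees for
the exhaustive DNF oracle; 50 small forests for the OOB recount; 10
seeded replicates for planted-term recovery; 40 null replicates with 50
outcome permutations of 50-tree forests for the calibration study; and
permuted refits at a quarter of the fitting schedule (a compute guard the
permutation stage applies by default, flagged in its output).

## Known limitations

* Only classification logic trees are ensembled; the original
  logic-regression GLM form (trees inside a linear predictor) is out of
  scope.
* No multiple-testing adjustment across implicants is applied; the
  permutation p-values are raw, and the selection effect above applies.
* Multi-allelic sites, phasing, imputation and X-chromosome dosage
  conventions are unsupported; VCF input must be biallelic with GT
  fields.
* The minor allele is oriented from the input sample itself when allele
  labels are absent; an exact 0.5 frequency ties toward the ALT allele
  (VCF) or the alphabetically first allele.

## A worked run

```{r}
library(logicgxe)

g <- system.file("extdata", "synthetic_genotypes.tsv", package = "logicgxe")
p <- system.file("extdata", "synthetic_phenotypes.tsv", package = "logicgxe")
gm <- read_genotypes(g, "tsv")
ph <- read_phenotypes(p)

qc <- apply_qc(gm, controls = ph$subject_id[ph$status == 0])
dat <- assemble_dataset(qc$genotypes, ph, scheme = "recessive")

set.seed(7)
fit <- logic_forest(dat, B = 50, control = anneal_control(iterations = 5000))
fit
imp <- importance(fit)
imp
pt <- permutation_pvalues(fit, terms = list(imp$pi$pi[1]), n_perm = 50,
                          imp = imp)
pt
confirm_pis(dat, as.list(head(imp$pi$pi, 3)))
```

The same flow, file-to-file, is available through `run_study()` with a
`run_config()`, or from a shell via the thin wrapper in
`inst/cli/logicgxe.R` (subcommands `simulate`, `qc`, `fit`, `permtest`,
`confirm`, `run-all`).
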