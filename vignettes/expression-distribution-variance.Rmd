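---
title: "Methods: the expression-distribution variance phenotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the expression-distribution variance phenotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gexvar)
```

## The phenotype and why preprocessing order matters

Most microarray analyses ask which genes differ between groups. `gexvar`
asks a different question: does the *shape* of a sample's whole expression
distribution differ? The readout is one scalar per array,

$$V_s = \frac{1}{G}\sum_{g=1}^{G}\big(x_{gs} - \bar{x}_s\big)^2,$$

the variance of all $G$ log2-transformed probe intensities of sample $s$
(population divisor; `overall_variance()` also offers the $G-1$ form, a
difference of order $10^{-5}$ at array scale). A coordinated dampening of
transcription compresses every expression level toward the grand mean and
lowers $V_s$, even when no individual gene moves far enough to be detected
on its own.

This phenotype dictates a two-branch pipeline:

* **Variance branch** — $V_s$ is computed on summarized, log2-transformed,
  *non*-quantile-normalized data, using *all* probes (no present-call
  filter). Quantile normalization forces every sample's distribution to be
  identical, so it would erase the phenotype by construction;
  `quantile_normalize()` followed by `overall_variance()` returning a
  constant across samples is asserted in the test suite as the formal
  statement of this incompatibility.
* **Differential-expression branch** — per-probe comparisons *are* run on
  quantile-normalized data, restricted to a present-call background, with
  raw $p < .05$ and fold change $\ge 1.1$ (both configurable; the
  fold-change boundary is inclusive, and fold change is the anti-logged
  difference of group mean log2 values, the standard convention for
  log-scale array data).

`run_pipeline()` hard-codes this branch rule and its report states which
branch fed each statistic.

## Statistical tests applied to the phenotype

The phenotype is standardized ($z$-scored) so effects read in SD units.
The reference set is configurable in `standardize()`; the pipeline default
is the full analyzed sample set. Recovery simulations in the tests use the
control group as reference instead, because a planted case deficit inflates
the pooled SD by $\sqrt{1 + d^2 p(1-p)}$ (about 2.4% at $d = 0.45$) and the
control reference makes the planted and recovered units coincide exactly.

* `compare_groups()` — unpaired $t$ (Student pooled by default; Welch by
  flag). Estimate = difference of group means, case minus reference.
* `variance_ancova()` — OLS with effect coding ($-1$ = affected group,
  $+1$ = control; $-1$ = batch 1, $+1$ = batch 2), subject age continuous,
  and all interactions among the requested terms. P-values are two-tailed
  Wald $t$-tests on coefficients. Under this coding the implied
  case-minus-control difference is $-2\beta_{dx}$, and with
  `terms = "diagnosis"` alone the diagnosis p-value equals the pooled
  $t$-test's (tested). Rank-deficient designs are reported with the aliased
  term names rather than silently dropped.
* `correlation_fisher()` — Pearson $r$ with the Fisher transform
  $z = \operatorname{atanh}(r)\sqrt{n-3}$ against the standard normal,
  two-tailed. Agrees with a 10,000-draw permutation p within Monte-Carlo
  error (tested).
* `spearman_corr()` — both the classical $1 - 6\sum d^2 / (n(n^2-1))$ on
  mid-ranks and the tie-corrected form (Pearson correlation of mid-ranks,
  identical to the textbook tie-term formula), each with the
  $t$-approximation p-value. Reporting both mirrors standard practice when
  ages are recorded in whole years and ties are guaranteed.
* `shapiro_normality()` — gates parametric vs rank-based reporting per
  experimental group.
* `median_split()` — dichotomizes a covariate at the median of its
  non-missing values; the boundary value joins the *older* group. With
  integer ages and an integer median this matches the convention
  "$\ge$ median = older"; missing values propagate as `NA` and are excluded
  from paternal-age analyses rather than imputed.

## List overlap and enrichment

`overlap_chi_square()` implements the Yates-corrected 2×2 chi-square

$$\chi^2 = \frac{N\,\big(\max(|ad-bc| - N/2,\, 0)\big)^2}{(a+b)(c+d)(a+c)(b+d)},$$

with the continuity term clamped at zero for near-independent tables and a
1-df upper-tail p-value (the standard two-sided test for a 2×2 table). It
matches the generic continuity-corrected implementation in `chisq.test()`
to six decimals over 1,000 random tables (tested).
`overlap_counts_chi_square()` accepts printed marginal counts so published
overlap tables can be re-analyzed without the underlying lists.

`enrich_sets()` replaces a hosted annotation service with a local test
against user-supplied GMT collections: one-sided hypergeometric upper tail
(Fisher), or the conservative EASE variant that removes one member from the
observed overlap before testing ($p_{EASE} \ge p_{Fisher}$ always; tested
against brute-force hypergeometric sums on universes up to $N = 20$).

## The synthetic cohort generator

No public cohort accompanies the analysis this pipeline operationalizes, so
the generator is first-class, tested code that encodes the hypothesized
mechanism — downregulation of transcriptional regulators compressing the
expression distribution — with known ground truth:

$$x_{gs} = m + \lambda_s\big(\mu_g - \delta_s \mathbb{1}[g \in R] - m + b_{g,\mathrm{batch}(s)}\big) + \varepsilon_{gs},$$

$$\lambda_s = \big(\lambda_0 + \beta_{dx}\mathbb{1}[\text{affected}_s] + \beta_{pa}\, z(\text{paternal age}_s)\big)\,\big(1 - c\,\mathbb{1}[\text{affected}_s]\big).$$

The contraction factor $\lambda_s$ scales each sample's deviations from the
grand mean $m$, so $\lambda < 1$ compresses the distribution while leaving
its mean untouched; the closed form
$E[V_s] = E[\lambda_s^2]\,(\mathrm{Var}(\mu) + f(1-f)\delta^2 + \sigma_b^2) + \sigma^2$
(`expected_group_variance()`) is the analytic oracle for every recovery
test. The regulator coupling $c$ drives both halves of the mechanism with
one knob: regulator probes $R$ (fraction $f$) are shifted down by
$\delta_s = c$ log2 units in affected samples *and* $\lambda_s$ is
multiplied by $1 - c$, so increasing $c$ simultaneously produces a
down-regulated regulator signature in the DE branch and a variance deficit
in the phenotype branch.

Default conditions (chosen once, as the study conditions the package
emulates):

| parameter | default | rationale |
|---|---|---|
| group sizes | 82 affected / 64 control | the cohort geometry analyzed |
| probe means $\mu_g$ | Normal(6, 2) log2 | $\mathrm{Var}(\mu) = 4$, a log-normal-like intensity distribution |
| residual $\sigma$ | 1 log2 unit | typical probe-level noise |
| presence threshold | 82 (linear) | gives an analytic present rate of 43.6%, matching the ~44% regime of blood arrays |
| paternal age | Normal(31, 5) years, truncated [18, 55], integer | median ≈ 31, making median-split behaviour realistic |
| missing paternal age | 4/82 affected, 7/64 control | the availability pattern of the emulated cohort |
| subject age | Normal(5.5, 2.1) / Normal(7.9, 2.2) years | affected group younger, so the subject-age ANCOVA covariate is non-trivial |
| scan batches | 2, balanced within group | two-machine scanning, balanced by design |

`dx_effect_for_sd_deficit()` converts a target deficit in within-group SD
units into the $\beta_{dx}$ that plants it, using the analytic
within-group phenotype SD
(`expected_phenotype_sd()`: finite-probe measurement noise
$(4\lambda^2 S \sigma^2 + 2\sigma^4)/G$ plus the between-sample term from
paternal-age-dependent contraction). The inhibitor-experiment generator
(`simulate_inhibitor_experiment()`) reuses the same machinery for a
4-condition × $n$=3 design in which high-dose conditions have $\lambda_0$
reduced by a configured amount.

What the generator deliberately does *not* emulate: probe-sequence effects,
probe-set naming, spatial artifacts, the heavy right tail of raw
intensities beyond log-normality, or correlated probe blocks. Passing
recovery tests therefore demonstrate that the *statistics* behave as
claimed under the stated mechanism, not that real arrays follow this
generative model. The raw scale of $V_s$ is arbitrary (no published value
exists to match); only standardized effects are interpreted.

## Cross-validation by balanced halves

`balanced_split()` halves a group deterministically: within each scan-batch
stratum, samples are sorted by paternal age and assigned serpentine
(A, B, B, A, ...). An odd stratum's mid-ranked sample is set aside into the
currently smaller half before the serpentine runs — taking the leftover
from the centre of the age ranking (rather than letting a truncated
serpentine orphan the oldest sample) is what keeps the half means within
the $\mathrm{SD}/\sqrt{n}$ sampling bound at cohort group sizes. For much
smaller groups (≈20 with two strata) integer ages make that bound
occasionally unattainable by any paired assignment; the weaker guarantee —
serpentine halves are several-fold closer in mean age than random halves —
holds throughout and is what the tests quantify. The seed is used only to
break exact-age ties.

`crossval_run()` reruns the requested analyses per replicate pair and
reports concordance (per-replicate estimates and p-values, sign agreement,
and the chi-square overlap between the replicates' down-regulated lists).
Concordance is reported, not gated: half-sample replicates have roughly
$\sqrt{2}$ less power, so a non-significant replicate of a true effect is
an expected outcome and the report keeps the estimates visible alongside
the p-values.

## Numerical choices and degenerate inputs

* Log2 floor: linear values below $2^{-4}$ are clamped before
  transformation (summarization can emit near-zero signals); the count of
  floored cells is logged.
* Quantile-normalization ties: tied values within a sample receive the
  mean of the reference values at the ranks they occupy — deterministic and
  order-independent; a constant sample is handled by this rule, never an
  error. The flattening property then holds exactly for continuous data and
  to the tie-averaging epsilon for coarsely rounded data.
* Zero-variance probes in `de_table()`: equal constant groups give
  $t = 0, p = 1$; unequal constant groups give $p = 0$. Zero-variance
  inputs to correlations are errors, as is standardizing against a
  zero-SD reference.
* Chi-square margins: a zero margin (empty or exhaustive list) is an error
  naming the degenerate margin rather than a `NaN`.
* Determinism: one master seed per simulation; identical configuration and
  seed give bit-identical cohorts and pipeline results documents.

## Problem sizes used by the test suite and acceptance script

Simulation-based checks run at reduced probe counts (300–4,000 probes;
effects and thresholds are scale-free, and type-I/power behaviour depends
on sample sizes, which stay at 82/64) with 400–1,000 replicates for
rejection-rate and power estimates. These sizes were chosen so the whole
suite completes in about a minute while keeping Monte-Carlo error well
inside the asserted tolerances (3 binomial SEs for rates, 3 empirical SEs
for means).

## Known limitations

* The phenotype is a global summary: it cannot localize *which* genes
  drive a variance change; that is what the DE branch is for.
* Batch effects are modelled (and effect-coded in the ANCOVA) but never
  corrected in the expression values, since distribution-altering batch
  corrections would contaminate the phenotype — a deliberate scope
  decision, not an oversight.
* The EASE/Fisher enrichment treats probes as exchangeable units; probe-to-
  gene collapsing, redundancy clustering of terms, and annotation
  management are out of scope (identifiers pass through unchanged).
* With no deposited cohort, published cohort-level statistics can be
  reproduced only where they are functions of printed numbers (overlap
  chi-square, correlation inference); cohort-dependent headline values are
  validated by parameter-recovery simulation instead.
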