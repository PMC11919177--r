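---
title: "Two-wave symptom networks: models, conventions, and validation"
author: "cognet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-wave symptom networks: models, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cognet implements a complete two-wave psychometric network analysis for
questionnaire studies of depression, anxiety, and negative cognition:
scoring and record-validity filtering, regularized Gaussian graphical
models with extended-BIC selection, centrality and bootstrap stability
analysis, permutation-based network comparison, and a directed
cross-lagged panel network (CLPN). Because raw questionnaire data of
this kind are rarely shareable, the package also ships a synthetic
two-wave generator with a *known* data-generating model, so that every
stage of the analysis can be validated against a recoverable ground
truth. This vignette explains the models, the conventions the package
fixes where the literature leaves room, and what the validation does
and does not establish.

## The constructs and the data

Seven construct scores are analysed per wave: PHQ (PHQ-9 depressive
symptoms, 9 items, 0–3), GAD (GAD-7 anxiety, 7 items, 0–3), the three
subscales of the 22-item ruminative response scale — SR (symptom
rumination), BD (brooding), RP (reflective pondering), each item 1–4 —
NAB (attention to negative information, 10 items, 1–5), and NAT
(negative automatic thoughts, 8-item short form, 1–5). All scores are
item sums. One naming note: the negative-attention-bias construct is
often abbreviated "NA" in figures; the package uses `NAB` because `NA`
is R's missing-value literal.

Records pass a validity filter before scoring (`apply_qc()`). The
exclusion rules are applied in a fixed order — unparseable record,
failed lie-detection item, any missing item response, response time
under 480 s (8 minutes, strictly), age/grade mismatch, outlier
construct total, missing demographic — and each excluded record is
attributed to the *first* rule it triggers, so the per-reason counts
are reproducible and conserve the input count exactly. Two of these
rules needed a concrete choice the screening conventions leave open:

* **Outliers.** The default flags any construct total with |z| > 3.
  The reference mean and sd can either be computed within the filtered
  sample (default) or supplied per construct (`outlier_ref`), the
  latter being the natural choice when screening against established
  norms or when batches are small (a within-sample |z| cannot exceed
  $(n-1)/\sqrt{n}$, so small batches can never trigger the rule).
* **Age–grade consistency.** By default ages 18–24 are accepted with
  no grade coupling; a per-grade age table can be supplied.

## The contemporaneous network model

Each wave's network is a Gaussian graphical model: nodes are the seven
constructs, and an edge is the partial correlation between two
constructs conditioning on the other five,
$\rho_{ij} = -\kappa_{ij}/\sqrt{\kappa_{ii}\kappa_{jj}}$ for precision
matrix $K = (\kappa_{ij})$. Zeros in $K$ are conditional
independences. $K$ is estimated by the graphical lasso, maximizing the
penalized log-likelihood

$$\log\det K - \mathrm{tr}(SK) - \lambda \sum_{i \ne j} |\kappa_{ij}|$$

over positive-definite matrices, where $S$ is the Pearson correlation
matrix of the scores. The diagonal is not penalized. The package's
solver is a coordinate-descent block algorithm (compiled code, warm
starts along the penalty path); its solutions agree with an
independent ADMM solver of the same objective to far better than
$10^{-6}$ in objective value, which the test suite verifies on random
problems.

Model selection follows the standard EBIC recipe: 100 penalty values
logarithmically spaced between $\lambda_{\max}$ (the largest absolute
off-diagonal correlation, at which the graph is empty) and
$0.01\,\lambda_{\max}$, with the extended Bayesian information
criterion

$$\mathrm{EBIC}_\gamma = -2\,\ell(\hat K) + E\log n + 4\gamma E \log p$$

minimized over the path ($E$ = number of nonzero edges, $\gamma = 0.5$
by default — the conventional compromise between sensitivity and
specificity). Two details are deliberate choices: the likelihood
$\ell$ is evaluated at the *penalized* estimate rather than an
unpenalized refit (simpler, and standard in the psychometric
toolchain), and EBIC ties resolve to the larger penalty (the sparser
model) because the path is searched from $\lambda_{\max}$ downward.
Off-diagonal entries below $10^{-8}$ in magnitude are treated as exact
zeros for support and density reporting. The package reports edge
*density* (nonzero pairs over $p(p-1)/2$); some reports label this
same quantity "sparsity" — 19 of 21 edges is a density of 0.90.

Scores enter as Pearson correlations of (implicitly standardized)
sums. Polychoric or nonparanormal input correlations are out of scope;
with 4- and 5-point items summed over 7–22 items per construct, the
Pearson treatment is the pragmatic standard.

## Centrality conventions

For undirected weighted networks the package computes strength,
closeness, and betweenness, raw and z-scored:

* **Strength**: $\sum_j |w_{ij}|$ — absolute weights, so negative
  edges count toward connectedness.
* **Closeness**: the *reciprocal* of the summed shortest-path
  distances to all other nodes, with edge length $1/|w|$. (Verbal
  definitions sometimes say "the sum of the distances"; the reciprocal
  is implemented so that larger = more central, consistent with how
  the measure is plotted and ranked.) A node that cannot reach every
  other node gets closeness 0.
* **Betweenness**: shortest-path throughput with fractional credit for
  tied shortest paths (Brandes convention), unordered pairs, lengths
  $1/|w|$.

Shortest paths are delegated to igraph; the test suite checks both
measures against an exhaustive simple-path enumeration oracle on all
random graphs up to five nodes. Z-scores standardize across the seven
nodes with the population (divide-by-$n$) denominator; a constant
column is mapped to zeros and flagged rather than producing NaNs.

For directed cross-lagged networks the centralities are incoming and
outgoing expected influence (IEI/OEI): *signed* sums of a node's
incoming/outgoing coefficients, excluding the autoregressive diagonal.
Signs matter here because a protective (negative) cross-lag should
offset a risk (positive) one.

## Accuracy and stability

Edge-weight accuracy uses the nonparametric bootstrap: `B = 1000`
resamples with replacement, the full estimator re-run on each,
percentile 2.5/97.5 intervals per edge. Replicates on which estimation
fails are dropped and counted.

Centrality stability uses the case-drop bootstrap: for each drop
proportion in a grid (0.05 to 0.75 in steps of 0.05), subsamples
without replacement are drawn, the estimator re-run, and the subsample
centralities correlated with the full-sample ones. The
correlation-stability (CS) coefficient is the largest drop proportion
at which that correlation is at least 0.7 in at least 95% of
subsamples, and 0 if no level qualifies. Three conventions are fixed
here: the grid ceiling is 0.75 (so CS = 0.75 is the strongest
reportable stability — a verbal description of "dropping 70%" pairs
with a reported 0.75 only under this grid); the correlation is
Spearman by default (robust to monotone scale changes across
subsamples, Pearson available); and a degenerate subsample centrality
(e.g. all betweenness zero) counts as *unstable* rather than being
dropped, which makes CS conservative. The usual reading applies: CS
above 0.5 is good, below 0.25 is inadequate. The per-level default is
`B = 250` subsamples, a runtime compromise; the edge bootstrap keeps
the conventional 1,000.

## Comparing the two waves

The permutation network-comparison test re-estimates both networks
under a relabeling null and compares (a) the absolute difference in
global strength (the sum of absolute edge weights) and (b) every
individual edge difference, with an omnibus maximum-difference
statistic. P-values use the add-one estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\mathrm{perm}})$, so
they are never exactly zero; per-edge p-values are Holm-corrected over
all 21 pairs by default (Bonferroni, BH, or none are available — the
choice is configurable because reports often leave it unstated). Note
an arithmetic consequence: with Holm over 21 edges, no adjusted
p-value can fall below $21/(1+n_{\mathrm{perm}})$, so edge-level
significance at $\alpha = 0.05$ requires $n_{\mathrm{perm}} > 420$;
the default is 1,000.

Two designs are supported. For independent groups, group labels are
permuted (the pooled rows are put in a canonical order first, which
makes the test exactly symmetric in its two arguments). For the same
respondents measured twice — the typical two-wave situation — the
default null swaps a respondent's two waves with probability 1/2,
which respects the within-person dependence that an independent-label
permutation would ignore. The independent permutation remains
available for parity with tools that only offer it.

## The cross-lagged panel network

The CLPN regresses each wave-2 construct on *all* wave-1 constructs
(including its own wave-1 value, the autoregressive path) with a lasso
penalty:

$$\hat\beta_{\cdot j} = \arg\min_\beta \tfrac{1}{2n}\lVert X^{(2)}_j -
X^{(1)}\beta\rVert^2 + \lambda_j \lVert\beta\rVert_1,$$

columns standardized beforehand so the coefficients are standardized
effects. Each target's penalty is chosen by ten-fold cross-validation
via glmnet with a deterministic fold assignment drawn from the run
seed; the CV-minimum rule is the default and the one-standard-error
rule is available. The lasso's exact zeros *are* the elimination of
small coefficients — no additional threshold is applied by default
(one is available). Autoregressive paths are estimated (dropping them
would inflate the cross-lags, since each wave-2 construct is strongly
predicted by its own baseline) but are flagged in outputs and excluded
from the IEI/OEI centralities, which summarize cross-construct
prediction only. In the unpenalized limit the fit agrees with the
ordinary least-squares normal equations, which the tests verify at
large n.

## What the synthetic generator emulates

`make_default_truth()` fixes a documented data-generating model:

* **Contemporaneous structure**: a 7×7 precision matrix with unit
  diagonal whose off-diagonal entries plant partial correlations —
  dense positive edges within the rumination triad (SR–BD 0.40, SR–RP
  0.30, BD–RP 0.30), a strong PHQ–GAD edge (0.35), symptom rumination
  and negative automatic thoughts tied to both symptom nodes (SR–PHQ
  0.25, SR–GAD 0.20, NAT–PHQ 0.20, NAT–GAD 0.20), NAB attached only
  through NAT (0.22), and exact zeros elsewhere. Every planted edge is
  at least 0.2 in magnitude, so support recovery is a well-posed
  target; the qualitative shape — rumination triad strongest, PHQ–GAD
  strongest outside it, NAB weakest — mirrors what two-wave studies of
  these constructs report.
* **Temporal structure**: $X^{(2)} = X^{(1)} B + E$ with
  autoregressive diagonal 0.4, planted cross-lags SR→PHQ (0.15),
  NAT→GAD (0.18), PHQ→GAD (0.12), GAD→SR (0.12), and diagonal residual
  covariance $0.5 I$ (which keeps wave-2 marginals near unit
  variance). All planted cross-lags are at least 0.1, again to make
  recovery a sharp criterion.
* **Items**: each construct's latent score is discretized into its
  scale's Likert items as
  `round(clip(center + half * 0.5 * (z + noise)))` with item noise sd
  0.8, chosen so that rescored totals correlate above 0.9 with the
  latent scores — high enough that the network machinery sees the
  planted structure, low enough that discretization is not a no-op.
  Absolute scaling of totals is immaterial downstream because networks
  are fit on correlations.
* **Quality problems**: lie-check failures, missing items, and
  too-fast completions are injected independently at 3%/4%/3% by
  default — modest rates typical of supervised survey screening — and
  recorded in a hidden ledger so tests can assert the filter removes
  exactly the corrupted records. Attrition between waves is simple
  random dropout.

Two consequences are worth stating. First, because the transition is
moderate (0.4 autoregression) and the residual noise substantial, the
wave-2 construct correlations are genuinely *attenuated* relative to
wave 1: the wave-2 network has the same planted topology but weaker
edges, and the comparison stage correctly reports a global-strength
difference on large simulated samples. This is a property of the
generator, not of any particular empirical study — real two-wave data
with stable traits typically show much more similar waves. Second, the
generator's item model is symmetric around scale midpoints, so
simulated prevalences above conventional screening cutoffs are higher
than in real student samples; prevalence cutoffs are configuration
(`cutoffs = c(PHQ = 10, GAD = 10)` by convention), and no default is
asserted to reproduce any published rate.

What passing tests therefore show: the estimators recover known sparse
structure, hold their nominal error rates, and are stable and
reproducible under the generator's Gaussian-latent, Likert-discretized
conditions. What they do not show: robustness to skewed or
zero-inflated items, severity-dependent attrition, or model
misspecification of the kinds real questionnaire data can exhibit.

## Numerical and reproducibility choices

* Glasso convergence: outer threshold $10^{-7}$ relative to the mean
  absolute off-diagonal of $S$, inner coordinate-descent tolerance
  $10^{-9}$; non-convergence raises an error rather than returning a
  stale estimate.
* Degenerate inputs error early with informative messages: correlation
  matrices that are not positive definite, constructs with zero
  variance (named), fewer than $p+1$ rows, case-drop levels leaving
  fewer than $p+1$ cases (skipped with a warning).
* All randomness flows from explicit integer seeds. The pipeline
  derives per-stage seeds from one master seed via a fixed
  congruential rule (`child_seed()`), so a configuration plus a seed
  reproduces every artifact byte-for-byte; stage timings are logged to
  a separate file to keep the summary deterministic.
* Problem sizes: the validation suite runs support recovery and CLPN
  recovery at n = 5,000 over 20 seeds, the comparison test's size
  check with 200 Monte-Carlo repetitions of 200 permutations at
  n = 500 per group, and stability at n = 5,000 (and n = 60 for the
  instability contrast) with 100 subsamples per drop level; the
  workflow demonstration uses a wave-1 sample of 2,709 with 760
  re-observed, matching the scale of the motivating design. These are
  the package's validation conditions, chosen to make the stochastic
  assertions sharp at desk scale.

## Known limitations

Pearson correlations on ordinal sums (no polychoric option); two waves
only (no graphical VAR or joint contemporaneous-plus-temporal model);
no bootstrapped difference tests between pairs of centralities; no
centrality-invariance permutation test; figures are not produced by
the pipeline — its canonical outputs are tables, and plotting is left
to the user.
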