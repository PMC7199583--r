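---
title: "Methods: multi-cohort mega-analysis, enrichment, and shared-pathway networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort mega-analysis, enrichment, and shared-pathway networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megapath)
```

## Overview

`megapath` combines two evidence streams about a regulator suspected of
opposing a disease: curated literature relations (regulator → target
edges with polarity and a reported disease direction for the target)
and a compendium of independent case/control expression cohorts. This
vignette documents the models, the tunable parameters and their
defaults, the synthetic-data generator, numerical edge cases, and the
design choices made where the design was genuinely open.

## Relation classification

Every admitted relation carries a polarity: `-|` (negative,
suppressive) or `-+>` (positive, stimulatory); rows without resolvable
polarity are rejected at parse time, with the rejection reason
retained. Classification is a pure function of (polarity, direction):

* negative polarity × target up in disease → **suppressed disease
  promoter**;
* positive polarity × target down in disease → **activated disease
  inhibitor**;
* matching signs → *concordant, excluded* from the contradirectional
  set;
* unknown direction → excluded and logged.

The disease-role vocabulary (`promoter`/`inhibitor`) maps onto
`up_in_disease`/`down_in_disease` before classification: a disease
promoter plays the same algebraic role as a gene overexpressed in
disease, so one classifier serves both the common-target and the
disease-role relation tables. When one target carries several relations
from the same regulator, the relation with the larger supporting
reference count wins; a polarity conflict with tied reference support
excludes the target rather than guessing. Reference weight is the only
arbiter available in a literature table, and refusing ties keeps the
classification deterministic.

The packaged fixture `synthetic_relations.tsv` is a synthetic emulation
of such a curated worksheet: 29 relations over 25 distinct targets plus
the regulator (26 genes in total, 1255 supporting references), of which
the common-target portion contains 13 suppressed disease promoters and
6 activated disease inhibitors. One disease-role target is spelled
`EDN1` (the standard endothelin-1 symbol); fixtures use the standard
symbol throughout. Gene identifiers are matched case-sensitively after
whitespace trimming; alias resolution is database-dependent and out of
scope.

## Effect sizes

For each study the effect size of a gene is the log2 fold-change
`LFC = mean(case) − mean(control)` of log2-scale expression. Input
matrices are assumed gene-level and log2 already (`assume_log2 = FALSE`
applies `log2(x + 1)` on load); probe collapsing and normalization are
upstream concerns. The LFC's uncertainty is the unpooled Welch standard
error `sqrt(s²_case/n_case + s²_control/n_control)` with unbiased group
variances — robust to unequal variances and to the extreme imbalance of
the default design (one cohort has 4 controls against 443 cases).
Singleton groups contribute variance 0 with a flag. A gene with zero
variance in both groups would take infinite weight downstream; its se
is replaced by one tenth of the smallest positive se among that gene's
studies (logged), or by equal weights if no study has positive se.

## Pooling and model selection

Fixed-effects pooling uses inverse-variance weights `w = 1/se²`;
random-effects pooling uses the DerSimonian–Laird moment estimator
`τ² = max(0, (Q − df)/C)`, `C = Σw − Σw²/Σw`, and re-weights
`1/(se² + τ²)`. Heterogeneity is reported as Cochran's Q, `df = k − 1`,
`ISq = 100 × (Q − df)/Q` clamped to 0 when `Q ≤ df`, and the upper-tail
χ² probability `Qp`.

Two deliberate choices:

* **The ISq rule, not a Qp threshold, selects the model.** `ISq = 0`
  (equivalently `Q ≤ df`) selects fixed effects, anything else random
  effects; `Qp` is reported but never gates. With `Q > df` the DL
  estimator gives `τ² > 0`, so the random model is only ever fitted
  when it differs from the fixed one.
* **Normal (z) p-values** for the pooled effect, standard
  inverse-variance practice; no Hartung–Knapp adjustment, REML, or
  publication-bias machinery (out of scope).

Under homogeneity Q is approximately χ²(k−1), whose median lies just
below k−1; the fixed model is therefore selected in roughly half of
homogeneous replicates (55% in the known-variance limit for k = 13),
less when small arms make the Welch variances noisy and over-disperse
Q. This is a property of the Q ≤ df clamp itself worth keeping in mind
when interpreting the selected model on real compendia.

`meta_analyze()` returns a classed `meta_result` with `print()`,
`summary()`, `coef()`, `confint()` and `as.data.frame()` methods;
`mega_analyze_genes()` maps it over a gene list and appends a BH column
(`p_bh`) as extra information — per-gene p-values are reported raw, and
no multiple-testing correction gates any decision.

## Covariate regression

`fit_mlr()` regresses a gene's per-study LFCs on total sample size
(case + control; case-only by option), study age in years, and country
(one-hot, most frequent country as reference, dropped with a warning
when only one country is present). The fit is unweighted OLS by
default — the inverse-variance weighted variant is behind
`weighted = TRUE`. Per-factor p-values are partial F-tests from
dropping each term, so the multi-level country factor reports a single
p-value; for 1-df numeric terms the partial F coincides with the usual
two-sided t-test.

One caveat the generator makes visible: when per-*sample* noise is
homoscedastic, the per-*study* LFC variance `σ²(1/n_c + 1/n_a)` is
strongly heteroscedastic across a design whose arms span 4–443, and it
correlates with the size and country covariates. Unweighted-OLS
t-tests are then anticonservative for those factors. The type-I
property of the regression is therefore assessed under its own sampling
model (iid LFC noise, no covariate effect), where the 5% level is
exact; on heteroscedastic cohort data the weighted variant is the
appropriate guard.

## Enrichment and the shared-pathway network

Fisher's exact over-representation uses the hypergeometric upper tail
`P(X ≥ overlap)` with population = universe size, successes = set size,
draws = query size. The background universe defaults to the union of
the loaded collection's members (the only self-consistent choice when
no snapshot of the source database is available) and can be overridden
by file. Set sizes are counted within the universe. BH-FDR q-values
with a pass/fail column at `q = 0.05`, and the Jaccard similarity
`overlap/(set + query − overlap)`, accompany each set. For reproducing
printed top-10 arithmetic, `jaccard()` operates directly on printed
(set size, query size, overlap) triples — e.g. `(544, 26, 17) → 0.031`
— independent of any universe restriction. Survival filtering keeps
`p < 1e-6` (strict), sorts by p with deterministic name tie-breaks, and
truncates to the top k (default 10).

Genes co-occurring in at least one surviving pathway are connected;
the edge weight counts shared pathways. Node statistics report the mean
± standard deviation of a gene's incident edge weights; "±" is read as
the *sample* SD (n − 1), with the population variant behind a flag.
Membership is taken from the full `p < 1e-6` surviving set (not just
the displayed top 10), mirroring the convention of counting shared
pathways out of all enriched ones.

## The synthetic-data generator

The generator's defaults are the package's study conditions:

* **Design**: 13 cohorts with arm sizes (30/9, 28/27, 49/58, 20/30,
  58/58, 58/58, 90/94, 30/80, 92/92, 4/49, 32/33, 4/443, 6/6),
  countries (Japan, Taiwan, USA ×2, China pattern as in
  `default_study_design()`), and study ages 1–13 years — the structure
  of 13 public GEO lung-adenocarcinoma case/control series, which are
  emulated, never downloaded.
* **Model**: per study s and gene g, the true effect is
  `δ_gs ~ N(true_lfc_g + covariate terms, τ²)`; controls are
  `N(baseline, σ²)` and cases `N(baseline + δ_gs, σ²)` on the log2
  scale. Gaussian log2 noise (not count models) matches microarray
  intensities. Defaults: `τ² = 0`, `σ = 1` (a typical log2 microarray
  residual SD), baseline 8 (mid-range log2 intensity).
* **Planted effects**: the regulator at −0.48, and ±0.5 (signed by
  literature direction) for the targets the expression arm is expected
  to confirm — 0.5 being a realistic confirmed-marker magnitude on the
  log2 scale; all other genes 0.
* Covariate effects enter the true study effect linearly, so the
  covariate regression is correctly specified in mean under the
  generator (variance heteroscedasticity remains, as discussed above).

`simulate_genesets()` plants exact query overlaps per set, optionally
restricted to a coverage pool so the union of overlaps covers exactly
a requested number of query genes (e.g. 24 of 26), with a repair pass
that guarantees the planted coverage whenever the overlap budget allows
it. `simulate_relations()` takes exact class counts rather than
fractions, because the planted composition must be matched exactly for
count-recovery tests. Fixed seeds give byte-identical outputs.

What the generator does *not* emulate: probe-level structure, batch
effects, inter-gene correlation, platform differences in gene coverage,
and non-Gaussian tails. Passing recovery tests therefore demonstrates
the estimators' correctness under the stated model, not robustness to
those real-data features.

## Numerical choices and degenerate inputs

* p-values are clamped to `(0, 1]` (never exactly 0).
* `jaccard(0, 0, 0) = 0` by convention.
* Ties in enrichment ranking break by set name; ties in relation
  de-duplication exclude the target.
* `k = 1` pooling returns the single estimate under the fixed model
  with heterogeneity flagged undefined.
* An exact-zero residual fit in the covariate regression reports
  machine-level p = 0 for its factors instead of NaN.
* Test-suite problem sizes: recovery experiments use 500 replicates of
  the 13-cohort design for the pooled estimator, 200 replicates of a
  50-study design for τ² recovery, and 1000 null replicates for the
  regression's type-I error — sizes at which Monte-Carlo error is well
  below the asserted margins.

## Limitations

* No REML/Paule–Mandel τ², Hartung–Knapp adjustment, or
  publication-bias diagnostics.
* No GO-graph ancestor propagation; gene sets are taken as given.
* No probe annotation, normalization, or GEO retrieval; inputs are
  gene-level log2 matrices.
* The enrichment p-values of a printed table cannot be reproduced
  without the original database's universe; only the Jaccard arithmetic
  is universe-free.
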