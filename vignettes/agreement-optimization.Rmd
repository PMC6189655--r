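---
title: "Optimizing interrater agreement and selecting raters for label curation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing interrater agreement and selecting raters for label curation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelagree)
```

## The problem

A labelled reference database built from expert opinion is only as good as
the agreement among the experts who labelled it. When a large panel — say 50
clinicians classifying hundreds of images into binary findings — disagrees,
group-level coefficients tell you *that* reliability is poor but not *who* is
responsible. `panelagree` measures two per-rater properties and turns them
into curation policies:

* **internal consistency** — does the rater agree with themself when shown
  the same item twice? (intrarater agreement over repeated presentations);
* **external consistency** — does the rater agree with the rest of the
  panel? (how early an iterative exclusion procedure removes them).

## The agreement model

All agreement is measured with Gwet's first-order coefficient AC1. For item
$i$, let $r_{iq}$ be the number of raters placing it in category $q$ of $Q$,
and $r_i=\sum_q r_{iq}$. Then

$$P_a=\underset{i:\,r_i\ge 2}{\mathrm{mean}}\ \sum_q\frac{r_{iq}(r_{iq}-1)}{r_i(r_i-1)},
\qquad
\pi_q=\underset{i:\,r_i\ge 1}{\mathrm{mean}}\ \frac{r_{iq}}{r_i},
\qquad
P_e=\frac{1}{Q-1}\sum_q\pi_q(1-\pi_q),$$

$$AC_1=\frac{P_a-P_e}{1-P_e}.$$

AC1 is preferred over kappa because its chance term is built from the
category marginals in a way that tracks the raw percent agreement even under
extreme prevalence, where kappa collapses (the "kappa paradox"). The
estimator tolerates missing cells: items with a single rating inform the
marginals but not $P_a$; items with none are ignored. A panel that is
unanimous in a single category has $Q_{\text{observed}}=1$ and is assigned
$P_e=0$, so perfect agreement is always coefficient 1.

The dispersion of the estimate is a **delete-one-item jackknife** standard
error: AC1 is recomputed leaving out each usable item in turn and
$SD=\sqrt{\frac{n'-1}{n'}\sum_i(AC_{1(-i)}-\overline{AC_1})^2}$. The
jackknife was chosen because the detection rule below only needs a
dispersion scale for the reliability estimate, it is assumption-free, and it
is directly testable against a brute-force loop. Closed-form variance
estimators exist but differ between software implementations; the jackknife
is this package's single, documented definition of "SD".

Intrarater agreement treats a rater's two occasions as a two-rater panel and
applies the same estimator, so internal and external consistency live on the
same scale. The conventional Landis–Koch benchmark applies: values above 0.6
are "substantial".

## Detecting discordant raters

For each rater $i$ of an $n$-rater panel with reliability $R_n$:

1. compute the reliability $R_i$ of the other $n-1$ raters, and its
   jackknife SD;
2. predict the $n$-rater reliability from $R_i$ with the Spearman–Brown
   formula, $R_j = \frac{kR_i}{1+(k-1)R_i}$ with $k=n/(n-1)$ — the
   reliability the full panel *should* have if rater $i$ were exchangeable
   with the rest;
3. form $\Delta R = R_n - (R_j - 2\,SD)$. If $\Delta R < 0$, the panel's
   actual reliability falls below even the lower end of the prediction
   interval: rater $i$ is *discordant*.

The interval half-width of 2 SD mirrors the usual outlier-screening
convention and is exposed as `ci_multiplier`. The SD attached to the
interval is the jackknife SD of the $(n-1)$-rater estimate, not transformed
through the Spearman–Brown map — a literal reading of "$R_j \pm 2SD$" whose
map derivative is ≈ 1 near the operating range for large panels. The
opposite tail ($R_n$ above the interval, i.e. the rater *improves*
reliability) is recorded as `beneficial` for information, but never acted
on: curation only removes raters who harm reliability. Ties ($\Delta R = 0$
exactly, as in a panel of identical raters) are not flagged — the inequality
is strict.

## The optimization loop

`optimize_agreement()` applies detection iteratively. Round 1 always runs,
whatever the starting reliability — the first identification is informative
for every feature. Each round excludes *all* raters flagged discordant in
one batch (observed practice: several raters per recognition round), then
recomputes AC1. The loop continues while the recomputed reliability stays
at or below `threshold` (default 0.6, the lower edge of "substantial";
convergence is the strict `> threshold`), new discordant raters keep
appearing, the panel stays at or above `min_raters`, and fewer than
`max_rounds` rounds have run. Non-convergence — the panel runs out of
discordant raters while still below the threshold — is a valid, recorded
outcome, not an error.

Numerical and edge choices:

* `min_raters = 3` because the leave-one-out step needs at least two
  remaining raters; a round whose batch exclusion would breach the floor is
  **not executed** (all-or-nothing batches; partial exclusion would impose
  an arbitrary ranking among tied raters) and the loop stops.
* `max_rounds = 50` is a safety cap against pathological loops; realistic
  panels converge or stall within ten.
* Excluded raters are never re-admitted.
* The procedure is deterministic: identical input and configuration give
  identical traces, which serialize losslessly to JSON (17 significant
  digits, bit-exact round-trip).

## Disagreement scores and selection policies

With $m$ total rounds, a rater first excluded in round $t$ receives the
disagreement score $m-t+1$: the most flagrant raters (round 1) score $m$,
stragglers score 1, survivors score 0. The score is a per-feature external
consistency measure; `aggregate_scores()` combines features by mean
(default, comparable when a rater misses a feature), sum, or max — the mean
and the sum differ only by the constant factor $n_\text{features}$ on
complete tables, so both are offered for reporting.

Three curation policies then select raters per feature:

* **A**: intrarater agreement strictly above 0.6 (internal consistency);
* **B**: disagreement score exactly 0 (external consistency);
* **C**: both, i.e. the intersection of A and B.

`evaluate_selection()` re-estimates AC1 per feature on the selected panel
and summarizes features as median and interquartile range, the conventional
report for skewed agreement distributions. Features retaining fewer than two
raters are unestimable and dropped with a warning rather than imputed.
`compare_methods()` compares the per-feature coefficient distributions:
a Shapiro–Wilk gate at $\alpha=0.05$ per group decides between a parametric
path (Welch one-way omnibus with pairwise Welch $t$ tests under Sidak-type
adjustment — the heteroscedastic Dunnett-T3 family) and a rank path
(Kruskal–Wallis omnibus with Dunn post hoc $z$ tests, tie-corrected, under
Bonferroni adjustment). The gate makes an otherwise subjective
normal/non-normal decision reproducible. Degenerate input — every group
constant — yields an explicit "undefined" report instead of a test.

## The synthetic panel generator

Real expert-rating panels of this kind are typically confidential, so
validation runs on seeded synthetic panels with known ground truth
(`panel_config()` / `generate_panel()`). The generative model is the
simplest one under which "discordant rater" is well defined — latent truth
plus independent rater error:

* each item has a latent binary truth drawn at the feature's prevalence;
* a rater reports the truth with probability equal to their accuracy,
  otherwise errs (symmetrically, or toward category "1" with a configurable
  bias);
* planted discordant raters simply have lower accuracy;
* second-occasion ratings equal the first flipped independently with a
  per-rater probability, modelling internal inconsistency.

Defaults mirror a large expert-labelling study design: 50 raters, 230
single-presentation items per feature, 35 repeated items, 25 binary
features, good-rater accuracy 0.9, one planted profile of 10 raters at
accuracy 0.55, replicate flip probability 0.1. Per-feature prevalence is
spread evenly over $[0.2, 0.8]$, covering rare through common findings, the
exact mix of real panels being unknowable. All randomness flows from the
single config seed.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real panels: correlated errors among raters
(schools of opinion), item difficulty heterogeneity, prevalence drift,
systematic presentation-order effects, and raters whose accuracy varies by
feature. Independence across raters makes the planted raters easier to
detect than colluding real-world subgroups would be.

## Validation problem sizes

The test suite exercises the pipeline at the following scales, chosen to
make the statistical assertions stable while keeping a full run fast:

* estimator correctness: 1000 random panels up to 8 items × 5 raters with
  missing cells, checked to $10^{-12}$ against an explicit-loop oracle;
* detection recovery: 20 seeds of the 50-rater × 230-item scenario with 10
  planted raters at accuracy 0.55 (mean sensitivity ≥ 0.8, specificity
  ≥ 0.9);
* selection ordering: 20 seeds at 50 raters × 230 items × 8 features with
  35 repeated items, adding noisy-replicate raters (flip 0.45) to half the
  planted raters and three concordant ones; the median ordering
  C ≥ max(A, B) ≥ original is required in ≥ 80% of seeds;
* first-round improvement: 20 seeds at 15 raters × 80 items with 3 planted
  raters (AC1 after round 1 ≥ initial in ≥ 95% of seeds).

## Limitations

The ΔR criterion inherits the Spearman–Brown assumption of parallel
(exchangeable) raters; with heavy contamination the "rest of the panel" is
itself unreliable and early rounds can misrank raters, which is why the
procedure is iterative. Detection power grows with the number of items:
small panels (≈ 100 items) yield wide jackknife intervals and a conservative
procedure. The disagreement score is not normalized across features with
different round counts $m$; comparisons across features should use the
selection outcome, not raw scores. Statistical comparisons of selection
methods treat features as independent observations, as is conventional,
although features rated by the same panel are not strictly independent.
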