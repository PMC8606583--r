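---
title: "Odds-ratio rule models for in-hospital mortality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Odds-ratio rule models for in-hospital mortality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oddsrules)
```

## The model

`oddsrules` estimates in-hospital mortality risk with an associative
classifier built from single-item rules. A clinical case is a set of
categorical items — (variable type, code) pairs drawn from ten types:
five admission-time demographics (ethnicity, gender, insurance type,
language, marital status; the *minimal* class) and five clinical types
(diagnosis, prescription, procedure, service, ward). Itemsets are sets:
repeated occurrences of a variable within a case collapse to one item,
and item identity is the exact code string. No normalization is applied
on purpose — near-duplicate codes that differ only in spelling or
whitespace are real data-quality signals, and the mined rules are one of
the few practical ways to surface them in a variable universe too large
to audit by hand.

For every distinct item the miner builds the 2×2 contingency table of
item presence against died/survived and computes the odds ratio
$\mathrm{OR} = ad/bc$. Unlike support/confidence association-rule
metrics, the OR measures *association*, not frequency, so rare but
strongly associated items (rare diseases, small subgroups) are retained.
Tables with a zero cell would give OR 0 or $\infty$; these rules are
discarded outright rather than patched with a continuity correction
(e.g. Haldane–Anscombe +0.5), keeping every retained OR a finite,
strictly positive cross-product of observed counts.

Significance is assessed with the large-sample normal approximation of
the log odds ratio using the Woolf standard error
$SE = \sqrt{1/a + 1/b + 1/c + 1/d}$ and the two-sided p-value
$2(1-\Phi(|\ln \mathrm{OR}|/SE))$. The filter keeps rules with
$p < p_{\max}$, strictly: a p-value exactly at the threshold is
excluded ("below" means below). With Bonferroni correction the
threshold becomes $p_{\max}/n_{\text{tests}}$, where
$n_{\text{tests}}$ counts the tests actually executed — candidates
remaining after the zero-cell discard, not the full variable universe.
That count is recorded in the model (`nTests()`) for audit, since the
choice of denominator is a genuine design decision rather than a forced
one.

Two boundary behaviors deserve explicit statement:

* **$p_{\max} = 0$.** A strict `p < 0` filter would keep nothing. The
  intended semantics of the zero setting is "keep only overwhelming
  associations", which is realizable because double-precision p-values
  of very large $|z|$ underflow to exactly 0 (near $|z| \gtrsim 38.5$,
  below the smallest subnormal). The filter therefore switches to
  `p == 0` at this setting. A corollary: Bonferroni correction cannot
  change a $p_{\max}=0$ model, since zero divided by any test count is
  zero. A second corollary is environment-dependence in principle —
  which p-values round to exactly zero depends on the floating-point
  environment — though all IEEE-754 double platforms agree.
* **Small datasets.** At a few thousand cases no $|z|$ reaches the
  underflow regime, so $p_{\max}=0$ models are legitimately empty and
  every case receives the neutral score (below).

## Prediction

A case $p$ is scored by the arithmetic mean $\mathrm{OR}_p$ of the odds
ratios of the rules whose antecedent item lies in the case's itemset,
and labeled high-risk iff $\mathrm{OR}_p \ge \delta$ (ties at the
boundary are high-risk). The arithmetic mean — not geometric, not a
mean of log-ORs — is the defining aggregation of this method; the
bundled worked example depends on it (five demographic ORs averaging
0.636, nine ORs averaging 5.3278).

A case to which *no* rule applies is given the neutral score 1, the
no-association odds ratio. This situation is not addressed by the
method's published description; the neutral score is this package's
gap-fill, chosen because it classifies as low-risk under any boundary
$\delta > 1$ (boundaries calibrated on imbalanced mortality data sit
above 1 in practice) and because it leaves scores on the OR scale. The
CLI logs each neutral-score assignment per case so the choice is
visible in operation.

## Evaluation protocol

`runGrid()` reproduces the full experimental protocol: for each
repetition the collection is split at random into 90% training and 10%
test cases — *unstratified*, matching the method's description; for
each configuration of $p_{\max} \in \{0\} \cup \{10^{-n}: n=0..10\}
\cup \{0.05\}$ (13 values) × Bonferroni on/off (26 configurations), a
model is mined on the training split, both splits are scored, and
ROC/AUC, rule counts, and mean applying-rules-per-case are recorded.
Ten repetitions of 26 configurations give 260 cells;
`aggregateGrid()` reports mean ± sd per configuration.

AUC is computed by the rank (Mann–Whitney) statistic,
$P(\text{score}_{\text{death}} > \text{score}_{\text{survivor}}) +
\tfrac12 P(\text{tie})$, which equals the trapezoidal area under the
empirical curve. The half-credit tie convention is stated explicitly
because ties are structural here: scores are means over a small shared
rule pool, so many cases share a score exactly.

The decision boundary is the threshold maximizing the Youden index
$J = \text{sensitivity} + \text{specificity} - 1$ over the distinct
observed scores; ties are broken toward the smallest optimal threshold
(the most sensitive operating point among equals). Calibration uses the
**training** split's ROC and is then applied to the test split. Which
split to calibrate on was an open choice; training-side calibration
avoids leaking test information into $\delta$ and is the conservative
default. Confusion metrics treat high-risk as the positive
(death-predicting) class. With ~1.8% mortality, small populations can
produce splits whose training or test side lacks one outcome class;
such cells are flagged `valid = FALSE` and reported rather than
silently dropped.

## The synthetic population generator

Real credentialed EHR databases cannot ship with a package, so all
testing rests on `generatePopulation()`: outcomes are
Bernoulli(`baseMortality`, default 0.0179, the mortality rate of large
emergency/critical-care populations), and items are sampled
*conditionally independent given the outcome* with survivor prevalence
$q$ and death-class prevalence $p = \rho q/(1-q+\rho q)$, which makes
the population odds ratio of each item equal its planted $\rho$
exactly. Conditional independence is deliberate: it is precisely the
regime in which single-item odds-ratio rules carry the full signal, so
planted-OR recovery and null calibration are clean acceptance surfaces.

Demographic families (gender, ethnicity, …) sample at most one
mutually exclusive category per case, with category probabilities
$q_k$/$p_k$ by outcome class; because each $p_k$ is pinned by its
planted OR, the death-class probabilities need not sum to 1 — the small
remainder means the category went unrecorded, mirroring missing
demographics in real records. Clinical items are sampled independently
(a case can carry many diagnoses).

`mimicLikeConfig()` fixes the study conditions once: 20 minimal-class
items across five families with mild planted ORs (0.47–4.59, anchored
at published demographic mortality associations), and clinical families
with mostly-rare items (survivor prevalences ~5·10⁻⁴ to 0.1, geometric
decay) whose planted ORs sweep 0.05–50 on a log grid, assigned through
a golden-ratio permutation so effect size is not confounded with
frequency. Scales: *small* = 5,000 cases / 110 items (fast protocol
checks), *medium* = 50,000 cases / 1,000 items (discrimination
experiments). The configuration object itself contains no randomness;
all draws flow from the single seed of `generatePopulation()` in a
fixed order, so populations are exactly reproducible.

What the generator does **not** emulate: co-occurrence structure
(comorbidity networks, treatment-diagnosis coupling), temporal ordering
of items, ICD-code semantics, and data-entry noise. Consequently,
passing tests demonstrate correctness of the machinery and its
statistical calibration under conditional independence — not clinical
performance on real data, where correlated items make single-item ORs
confounded estimates of each item's own effect.

## Numerical and degenerate-input choices

* Strict `p < t` filtering; `p == 0` at $p_{\max}=0$; ties at the
  threshold excluded.
* Zero-cell tables are a signalled `NA` from `oddsRatio()` and a
  contract violation in `logOrTest()` (mining discards them first).
* Scores, ORs, and p-values are kept at full double precision; the
  published 2–3-decimal displays happen only in formatting.
* Empty itemsets are legal everywhere: such cases score 1 and classify
  low-risk; no case is ever excluded.
* Unlabeled cases (unknown outcome) are legal as *prediction* input —
  the bundled fictional patient is one — and rejected by mining and
  evaluation, which need outcomes.
* Mining is fully deterministic; only `generatePopulation()` and
  `splitCases()` consume seeds, and both restore the caller's RNG
  state.
* Rule tables are sorted by (variable type, code) so models, reports,
  and JSON serializations are byte-stable; model JSON uses a canonical
  key order and round-trips byte-identically.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` exercise: the worked
contingency table and fictional patient (exact values); the 26×10 grid
on the small population; planted-OR recovery ($q=0.3$, $\rho=3$) over
100 populations of 100,000 cases; null calibration over 2,000
planted-null variables ($q=0.2$, 20,000 cases per population) with
family-wise control checked over 20 populations of 500 null variables;
and full- vs minimal-model test AUC on three medium populations. These
sizes were chosen as the smallest that give the binomial margins needed
by each check (e.g. ~360 deaths per null population keep the normal
approximation of the log OR accurate at the 5% tail).

## Limitations

Single-item antecedents only: multi-item rules would capture
interactions but erode the one-variable-one-rule interpretability that
motivates the method, and are out of scope. All rules are associations,
not causal effects; confounding (age behind insurance type, ICU
admission behind ward) is expected and, for dataset exploration,
informative. Continuous and rapidly changing measurements (vitals, labs)
are not modeled — items are slowly changing categorical facts. And the
decision boundary is a single global operating point; applications
needing other sensitivity/specificity trade-offs should re-derive
$\delta$ from the ROC rather than reuse the Youden point.
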