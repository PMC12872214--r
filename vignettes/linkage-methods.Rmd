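---
title: "Evaluating record-linkage methods on deidentified EHR cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating record-linkage methods on deidentified EHR cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkehr)
```

## The problem

Two electronic health record extracts describe overlapping sets of
patients — here, a multiple sclerosis cohort held by a hospital system and
its deidentified representation in a national registry — but share no
direct identifier. Linking them must rely on indirect fields: sex, date of
birth, nationality, region, coverage status, facility, the first MS
diagnosis date, and set-valued clinical histories (other ICD-10 diagnoses,
medications, admission dates). Because no reference standard exists for the
real pairing, any linkage method has to be validated first in a setting
where the truth *is* known. `linkehr` implements that validation design: a
**clone-and-deidentify simulation** in which a dataset is linked against a
value-identical copy of itself under fresh record ids, so every true match
is known and every method can be scored with a full confusion matrix —
together with a synthetic cohort generator so the whole experiment runs
without access to any real patient data.

Three method families are implemented behind one evaluation surface:

* **deterministic** — a pair matches iff it agrees exactly on every field
  of a rule;
* **probabilistic (Fellegi–Sunter)** — pairs are scored by summed
  log-likelihood-ratio weights of per-field agreements, with the weights
  estimated by EM, and classified by threshold or one-to-one assignment;
* **machine learning** — pairs become similarity-feature vectors and a
  classifier (knn, logistic, neural network, random forest) labels them.

## The Fellegi–Sunter model and its EM estimator

For a candidate pair, let $\gamma_k \in \{0,1\}$ indicate agreement on
comparison field $k$. The model is a two-class conditional-independence
mixture: with probability $\lambda$ the pair is a true match and
$\gamma_k \sim \mathrm{Bern}(m_k)$; otherwise
$\gamma_k \sim \mathrm{Bern}(u_k)$. The *m-probability* is the chance a
field agrees given a true match (eroded by data errors); the
*u-probability* is the chance it agrees coincidentally. EM alternates

$$g_j = \frac{\lambda \prod_k m_k^{\gamma_{jk}} (1-m_k)^{1-\gamma_{jk}}}
            {\lambda \prod_k m_k^{\gamma_{jk}} (1-m_k)^{1-\gamma_{jk}}
             + (1-\lambda) \prod_k u_k^{\gamma_{jk}} (1-u_k)^{1-\gamma_{jk}}}$$

with $\lambda = \bar g$, $m_k = \sum_j g_j\gamma_{jk} / \sum_j g_j$,
$u_k = \sum_j (1-g_j)\gamma_{jk} / \sum_j (1-g_j)$. A pair's score is
$S = \sum_k [\gamma_k \log_2(m_k/u_k) +
(1-\gamma_k)\log_2\{(1-m_k)/(1-u_k)\}]$; $S > 0$ means the pattern is more
likely under the match class. The one-to-one step then selects pairs in
descending score order so that no record is linked twice.

Numerical choices, all assertable in the test suite:

* probabilities are clamped to $[10^{-6}, 1-10^{-6}]$ so no weight is
  infinite; initialization $m_k = 0.9$, $u_k = 0.1$, $\lambda = 0.1$;
  convergence when the largest parameter change drops below $10^{-6}$, cap
  1000 iterations (a warning, not an error — at very low match prevalence
  the parameters can drift slowly along the clamp);
* the observed-data log-likelihood is computed via log-sum-exp and is
  non-decreasing across iterations on every input;
* label switching is resolved by calling the class with higher
  $\sum_k \hat m_k$ the match class;
* vectors are collapsed to unique agreement patterns before iterating, so
  the cost per EM step is the number of distinct patterns, not pairs;
* comparison fields must exclude the block fields: within a block the
  blocking fields agree by construction and a constant-1 column carries no
  information for the mixture.

**Why greedy one-to-one?** Greedy selection in descending score order with
a deterministic tie-break (ascending id pair) is $O(P\log P)$, reproducible,
and — whenever the true pair strictly dominates each record's
alternatives, as it does in the clone design with quasi-unique dates — it
coincides with the exhaustive maximum-total-score assignment, which the
suite verifies against a branch-and-bound oracle on small instances. On
adversarial score patterns greedy is a 1/2-approximation; the package
exposes `one_to_one_assign(..., method = "exact")` so the deficit can be
measured where it matters.

## Agreement and missingness conventions

A blank scalar cell is *missing*; a blank set-valued cell is the *empty
set*, i.e. "no clinical event on record" — a value, not a gap. Two missing
values never agree (the standard conservative convention: shared
missingness must not manufacture matches), and consequently any comparison
involving a missing value contributes $\gamma = 0$. Set-valued fields agree
when they share at least one element (configurable to full set equality);
two empty sets share no event and do not agree under intersection
semantics. ML similarity features differ deliberately: they measure
*similarity*, not agreement, so two empty sets — identical values — score
Jaccard 1, dates score $1/(1+|\Delta\text{days}|)$, and categoricals score
their exact-agreement indicator.

## What the synthetic generator emulates

`cohort_config()` defaults describe the study conditions the package's
experiments are modelled on: source A has 2642 records; source B
represents $2247/2642 \approx 85\%$ of them (round-half-up of
`overlap_fraction * n`), under fresh ids; ages are Normal(34.4, 11) years;
diagnosis and admission dates fall in 2016–2023. Categorical frequencies
follow truncated geometric distributions $p_v \propto q^{v-1}$ whose ratio
$q$ is set per field so that coincidental agreement spans the observed
real-data-like range — sex (two levels, $q=0.5$, i.e. a 2:1 imbalance as
typical of MS cohorts) agrees by chance 56% of the time and is nearly
uninformative, nationality ($q=0.026$, one dominant value) 95%, while
quasi-continuous dates almost never agree by chance. This heterogeneity is
what makes the estimated u-probabilities differ across fields, which the
weighting exploits. Set-valued fields draw $1+\mathrm{Poisson}$ sizes, so
every record has at least one diagnosis, medication and admission — the
cohort is by construction a diagnosed, treated MS population, and this is
also why an uncorrupted clone agrees with its source on *every* field.

The error model is necessarily invented (the original study design cloned
real data): each B-side copy corrupts each field independently — category
swaps drawn from the field's own frequency distribution, date shifts of
$\pm U\{1..30\}$ days, one set element dropped or added, or the value lost
entirely (missingness). The per-field disagreement rate among truth pairs
therefore converges to the configured corruption+missingness rate, which is
exactly what makes EM's m-probability recovery a testable claim. What the
generator does **not** emulate: correlated errors across fields,
systematic cross-source coding differences, duplicate patients within one
source, and informative missingness. Perfect scores on the clean clone are
therefore a *structural* guarantee of the design, not a claim about messy
real-world extracts; the corrupted-cohort experiments probe robustness, but
only under independent errors.

Reproducibility uses a single global seed feeding derived per-record
streams (a Lehmer-style reseeding below $2^{31}$), so the same config and
seed give byte-identical cohorts regardless of generation order.

## Evaluation conventions

The confusion universe is the full cross product $|A| \times |B|$, with
$TN = |A||B| - TP - FP - FN$ computed arithmetically — millions of pairs
are never materialized (single-variable sweeps count candidates from
frequency tables). Sensitivity and PPV carry Wilson score 95% intervals,
chosen because the interval behaves at the 0/1 boundaries that perfect
linkage produces. $F_1 = 2 \cdot \mathrm{Sens} \cdot \mathrm{PPV} /
(\mathrm{Sens} + \mathrm{PPV})$; undefined rates (e.g. PPV with no
predicted positives) are flagged `NA`, never silently 0, and $F_1$ is 0
when sensitivity is 0. Tabulated percentages round half-up at two decimals;
truth-free match rates report count/$|B|$ at one decimal. Averages across
rules are unweighted arithmetic means of $F_1$ percentages. Wall-clock
runtimes are logged per engine call but never asserted — they are
hardware, not science.

## ML design choices

The "fields with higher impact" selection rule is operationalized as:
keep fields whose single-feature $F_1$ (threshold 0.5) on the training
labels exceeds a floor (default 0.2); the rule is computable, logged, and
configurable. "All possible pairs" is quadratic, so classification mode
uses the full cross product only up to 500 records per side; above that it
takes blocked candidates plus truth plus non-matches sampled at 10:1 per
match with the run's seed. The 75/25 split is stratified by label; the
bootstrap resamples *training* pairs only, keeping the test target fixed,
and redraws single-class resamples (counted). Hyperparameters are
conventional small-data defaults — knn $k=5$; L2-penalized logistic
regression; one hidden layer of 32 units, at most 500 epochs; 100 trees —
with features standardized for the scale-sensitive families only. Class
prediction uses probability 0.5; the probability itself is also emitted.

## Problem sizes used by the shipped analyses

The numbered scripts under `analysis/` run the full experiment at the
default cohort size (n = 2642); the ML step uses an 800-record subcohort
so that 100 bootstrap refits of all four families stay tractable on a
laptop. The test suite and the acceptance script use n = 2000 for the
clone-simulation checks and n = 5000 comparison vectors for EM parameter
recovery — sizes at which every structural claim is already stable.

## Known limitations

* Binary agreement only inside Fellegi–Sunter (no graded string-similarity
  levels, no three-state missing category); the documented extension would
  add a "missing" comparison level rather than folding it into 0.
* Greedy one-to-one assignment is exact only under score dominance (see
  above).
* The generator's independence assumptions understate real-world error
  structure; specificity-style quantities computed over the full cross
  product depend on a universe convention that published tables do not
  always share.
* EM u-probabilities are estimated over *blocked* candidates, so they are
  conditional on the block — informative blocking shrinks the apparent
  distinctiveness of fields correlated with the block fields.
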