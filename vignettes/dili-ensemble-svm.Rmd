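---
title: "Predicting drug-induced liver injury from adverse-event signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-induced liver injury from adverse-event signals: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dilisvm)
```

## The problem and the model

Spontaneous adverse-event reporting systems accumulate millions of reports
linking marketed drugs to clinical events. Disproportionality analysis
asks, for a drug–event pair, whether the pair is reported more often than
the drug's overall reporting volume and the event's overall frequency
would predict under independence. `dilisvm` uses this signal to *label*
drugs — hepatotoxic versus hepatically clean — and then learns a
structure-based classifier over molecular descriptors, so that the label
source (post-marketing reports) is decoupled from the prediction input
(computable compound attributes). The key assumption is the standard QSAR
premise: compounds with similar physicochemical and structural profiles
tend to share adverse-reaction liability. A second, pharmacovigilance-side
assumption is that all events in a report are attributable to its single
primary-suspect drug; concomitant medications are ignored.

### Disproportionality statistics

For a drug and an event class, the summarized report matrix yields the
2×2 table (a = pair count, b = drug's other events, c = event's other
drugs, d = the rest). The relative reporting ratio

$$\mathrm{RRR} = \frac{a\,N}{(a+c)(a+b)}, \qquad N = a+b+c+d,$$

is exactly 1 under row–column independence. Significance comes from the
Fisher exact test, i.e. the hypergeometric tail with all margins fixed.
Sidedness is not dictated by the cohort rule itself; we default to the
one-sided *greater* alternative because the positive rule already demands
enrichment (RRR > 1), and expose the two-sided variant by flag. No
multiple-testing correction is applied by default — the labeling rule is
stated on raw p-values — but Benjamini–Hochberg is available. A table with
an empty row or column margin raises an error rather than silently
returning 0/0.

### Cohort rules

Positives: at least 13 reports in the target event class (inclusive), RRR
strictly above 1, p strictly below 0.05. The report floor's derivation is
not documented in the source method; it is a parameter with 13 as default.
Negatives: exactly zero reports in the class and at least 10 years on the
market, operationalized through a user-supplied market-years table because
"year of patent" provenance (patent vs. approval) is ambiguous; we treat
market age as input data. The two rules are mutually exclusive by
construction (≥ 13 vs. 0 reports).

### The ensemble

With `n_pos` positives and a somewhat larger negative pool, each of
`n_trials` (500 in the reference protocol) balanced trials draws `n_pos`
negatives without replacement, splits each class 90/10 (test size
`ceiling(0.1 · class size)`, so 155 splits into 139 train / 16 test), and
fits an SVM after recursive feature elimination on the training split
only. Preprocessing — degenerate-descriptor removal, median imputation,
centering/scaling — is refitted inside every trial on its training
compounds, so no held-out information leaks into scaling or ranking.

The SVM is an L2-regularized hinge-loss machine solved by dual coordinate
descent (compiled code, cyclic sweeps, hence deterministic); class
probabilities are Platt-scaled decision values, with the sigmoid fitted on
the training decision values by a stabilized Newton iteration. The linear
kernel is the default: it is what makes weight-based RFE well defined
(importance = squared weight), and the resulting feature ranking is
interpretable. An RBF kernel is available; its RFE importances fall back
to seeded permutation importances on the training hinge loss.

RFE uses a halving schedule from the usable feature count down to 10
(configurable); the final ranking is the last surviving set ordered by
importance followed by the eliminated blocks in reverse order. Ranking a
trial once per `cost` and reusing it across `top` values is exact, not an
approximation, because the top of the ranking never depends on how far
elimination continued below it.

Per trial and per (cost, top) cell we record AUC and the confusion metrics
at the trial's decision probability — the threshold maximizing Youden's
J (sensitivity + specificity − 1) on the held-out ROC. Candidate
thresholds are the observed scores (classification is strictly
`probability > threshold`); among maximizers the highest candidate is
taken and the reported threshold is the midpoint to the next distinct
score, which centers it between the classes. Trials whose held-out set
degenerates to a single class have no ROC; they are flagged and excluded
from that cell's averages with a logged count. Cell averages are plain
arithmetic means; the best cell maximizes averaged AUC with ties broken by
smaller `top`, then smaller `cost` (parsimony). The default cost grid is
{0.01, 0.1, 1, 10, 100} and the default top grid {5, 10, 15, 20, 30, 50,
100, 200, 400, p}.

### Consensus and the final model

The selected top sets differ across trials; features are ranked by their
selection frequency over all trials at the best cell, and the most
frequent `top` features form the consensus set. Frequency ties are broken
by better (numerically smaller) mean within-trial rank, then by name — a
deterministic rule we chose because "better rank wins" is the only
scientifically sensible reading of a rank-based tie-break. The final model
refits preprocessing and the SVM on the *full* labeled pool (all positives
plus all negatives) restricted to the consensus features; the residual
imbalance is absorbed by inverse-class-frequency weights on `cost`, which
approximates the balanced objective while using every labeled compound.
The reference method does not state what the final model is trained on;
this choice is recorded in the model's provenance. Its decision threshold
defaults to the mean per-trial Youden threshold at the best parameters —
we read the "averaged probability separating the classes" as a best-cell
average, and expose it as an argument for callers who prefer a different
cut.

## Tunable parameters

| parameter | default | units / range | rationale |
|---|---|---|---|
| `min_reports` | 13 | reports | cohort rule as stated; inclusive |
| `rrr_gt`, `p_lt` | 1, 0.05 | — | strict inequalities per the rule |
| `min_years` | 10 | years | market-age floor for negatives |
| `n_trials` | 500 | trials | reference protocol; reduce for desk scale |
| `test_fraction` | 0.1 | fraction | 90/10 split, ceiling rounding |
| `cost` grid | 0.01…100 | — | decades around 1; penalty/margin trade-off |
| `top` grid | 5…p | features | brackets the 10–20 region that consensus models typically land in |
| RFE schedule | halving to 10 | features | geometric, ≤ log2(p) fits per ranking |
| kernel | linear | — | weight-based RFE, interpretability |
| DCD `tol`, `max_passes` | 1e-4, 2000 | — | projected-gradient stop; deterministic cyclic sweeps |

## What the synthetic generators emulate — and what they do not

`generate_reports()` draws each report's drug from configurable weights
and its event from the drug's event distribution; planted pairs multiply
the background event probability by a relative-risk factor and renormalize,
so multiplier 1 is the exact independence null and the truth record carries
closed-form expected counts. It does **not** simulate MedDRA vocabulary
structure, duplicate case versions, demographic fields, or
reporting-over-time dynamics — a green signal test establishes correct
disproportionality arithmetic and power on a clean generative null, not
robustness to real FAERS messiness (name freestyle, case deduplication).

`generate_descriptors()` draws standardized Gaussian features; the first
`n_informative` carry a between-class mean shift of `effect_size` standard
deviations and are drawn independently, while the remaining noise features
get block correlation (pairwise ρ, default 0.3 in blocks of 10) emulating
the heavy redundancy of large descriptor panels. Planting the informative
features independently of the noise blocks is deliberate: a noise feature
correlated with a shifted one would itself be class-informative in the
multivariate sense, making "recovery of the planted set" ill-posed. Real
descriptor distributions are heavier-tailed, discrete in places, and
correlate with the signal — a green recovery test establishes that the
ensemble-plus-consensus machinery finds planted multivariate structure,
not that any particular descriptor family is causally linked to
hepatotoxicity. Scale defaults mirror the reference cohorts (155/164
compounds, 818 features); tests run reduced profiles (50–100 trials, 200
features) purely for runtime.

## Numerical choices and degenerate inputs

* Dual coordinate descent stops when the largest projected-gradient
  violation in a sweep falls below 1e-4; sweeps are cyclic, so a fit is a
  pure function of its inputs and the whole grid search is bit-reproducible
  from the master seed (per-trial sub-seeds are derived arithmetically and
  kept within 32-bit range).
* The bias is handled as an augmented constant column, i.e. lightly
  regularized, the common trick in linear-SVM solvers.
* Platt scaling uses smoothed targets and a backtracking Newton iteration;
  on separable data the sigmoid is steep and probabilities saturate, which
  is expected and harmless for ranking-based metrics.
* Median imputation and standardization parameters are stored and reapplied
  at prediction time; applying them to the fitting set reproduces the
  training matrix bit-for-bit.
* Duplicate descriptor columns keep the first name in column order;
  all-constant columns are dropped, and a matrix that loses every column
  errors out rather than proceeding.
* PPV with zero predicted positives is `NA`, never 0; single-class held-out
  sets flag the trial instead of producing a degenerate AUC.
* Importance ties in RFE and frequency ties in consensus break
  deterministically (by name, and by mean rank then name, respectively).

## Known limitations

* Case-version deduplication and other FAERS ingestion realities are out of
  scope; the reader supplies a clean report table in one of two documented
  dialects.
* The RDKit-based descriptor backend is a stand-in: its panel differs from
  proprietary descriptor software, so feature *identities* found on real
  data are not comparable across backends, only the methodology is.
* Undersampling discards a few negatives per trial rather than reweighting;
  that is the stated protocol, and the ensemble averaging is what restores
  the information.
* Platt probabilities are fitted on training decision values (not nested
  CV); with small trials this mildly optimistic calibration affects the
  absolute threshold value, not the ROC-based model selection.
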