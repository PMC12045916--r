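---
title: "Identifying lung cancer screening orders: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying lung cancer screening orders: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcscreen)
```

## The classification rule and its assumptions

`lcscreen` decides, for each chest imaging order, whether the *ordering
provider intended* lung cancer screening (LCS). It is a deterministic
keyword system, not a statistical model: there is no training step, no
threshold to tune, and no probability attached to a call. That choice fits
the data it reads — radiology orders are short, formulaic, and written
against a known vocabulary — and it makes every call auditable: each
`lcs_call` carries the exact term hits, with field and character offsets,
that produced it.

The rule assumes:

* **The order, not the report.** Only order-time text is read (procedure
  name, Reason for Exam, Clinical History). The radiology *report* and the
  wider chart are out of scope; a scan whose order text is silent about its
  indication is `unable`, not guessed.
* **Setting is structured data.** ED/inpatient status arrives as an input
  column; it is never inferred from text.
* **Codes gate, text decides.** CPT codes define scope only. Even the
  LCS-specific codes (G0297, S8023, 71271) do not auto-classify a scan as
  screening — unreliability of those codes is precisely the problem the
  classifier addresses, so the text rules always make the call.
* **The veto.** A screening call requires screening language *and the
  absence of* diagnostic or Fleischner (nodule-surveillance) language.
  When both occur, non-screening wins. The alternative — treating the
  conflict as `unable` — would shrink the classified set without making
  "screening" calls any cleaner; the veto maximizes the positive
  predictive value of the screening label, which is the metric users of a
  screening cohort care about most. Screening calls are therefore not
  claims that the patient was asymptomatic, only that the order reads as
  screening with nothing pointing the other way.
* **`unable` is a first-class outcome.** An in-scope scan with no hit in
  any term set cannot be classified. Downstream analyses must pick an
  explicit policy: drop those scans (`exclude_unable`, the primary-analysis
  convention) or count them as non-screening (`unable_as_nonscreening`).
  PPV is invariant to this choice — unable scans are never called
  screening — while NPV and sensitivity can move; both policies are
  implemented and reported.

## Text normalization and matching semantics

All matching happens on normalized text: lowercased, hyphens and slashes
mapped to spaces, whitespace collapsed. Clinical text writes "low-dose",
"low dose" and "f/u" interchangeably, so the normalization folds those
variants together; it is idempotent, and spans always refer to the
normalized string.

Tokens are maximal runs of letters and digits. Three term shapes exist:

* whole-token terms (`ldct`, `lcs`, `cough`) never match inside longer
  words — `calcs` is not `lcs`;
* token-prefix terms, written with a trailing hyphen (`scr-`), match any
  token beginning with the stem: `screen`, `screening`, `scr`, but never
  `describe` or `sarcoidosis`, where the letters appear mid-token. The
  trailing-hyphen spelling is the standard wildcard notation for this
  family of abbreviations; prefix-of-token (rather than raw substring) is
  this package's reading of it, and it is configurable by editing the term;
* multi-word terms (`low dose`, `shortness of breath`) match as sequences
  of adjacent tokens separated by single spaces — `chest, pain` does not
  match `chest pain`, because the comma breaks adjacency.

Four boilerplate phrases ("Is this procedure to screen for malignancy?",
"This study is not intended for lung cancer screening.", "HCC screening.",
"Not for initial screening.") contain screening-like tokens that say
nothing about LCS intent. They are masked before screening-term matching:
each occurrence (terminal punctuation ignored) is overwritten with a
same-length run of `#`, a character that can match nothing and breaks
token runs. Same-length replacement keeps every other hit's offsets valid
against the original normalized text, which matters for audit trails.
Masking is applied per field and only gates *screening* terms; the
shipped phrases contain no diagnostic vocabulary, so diagnostic matching
reads the unmasked text.

The diagnostic term list shipped as default (cough, hemoptysis, chest
pain, weight loss, dyspnea, shortness of breath, wheezing, hoarseness,
fatigue, pneumonia, fever, night sweats) is seeded from the common
presenting symptoms of occult lung cancer in ambulatory care. It is a
documented starting point, not a validated instrument: real deployments
are expected to extend it iteratively as chart review surfaces new
vocabulary, which is why every term set is replaceable through
`lcs_lexicon(overrides)` or a YAML file, with the lexicon version or
override digest recorded in each run manifest. The four Fleischner
spellings (`fleischner`, `fleishner`, `fleichner`, `fleischer`) cover the
misspellings plausibly produced by hurried order entry; same mechanism to
extend.

## Deduplication

Re-extracted studies can appear twice under fresh accession numbers, so
duplicates are defined by (`patient_id`, `exam_date`, CPT code set,
`procedure_name`) — the most conservative key that cannot merge two
distinct same-day studies of different type — and collapse to the first
occurrence, with every removal logged. The key is a design choice;
narrower keys (e.g. dropping `procedure_name`) would merge legitimate
same-day pairs.

## Accuracy metrics and intervals

Validation crosses calls with chart-review gold labels; screening is the
positive class. Confidence intervals are exact Clopper–Pearson, computed
in the beta-quantile form (lower `qbeta(a/2, k, n-k+1)`, upper
`qbeta(1-a/2, k+1, n-k)`, with the k = 0 and k = n boundaries pinned to 0
and 1). Exact intervals were chosen over Wilson or normal approximations
because several validation denominators are small (a specificity
denominator in the twenties), where approximate intervals undercover. A
zero-denominator metric is reported as flagged-undefined, never silently
as 0 or 1, and never as an exception: degenerate tables are legal inputs.

Survey-weighted variants replace counts with weight sums, so point
estimates refer to the population the sampling weights map onto. For the
interval, the denominator group's Kish effective sample size
`(sum w)^2 / sum(w^2)` feeds effective successes `p * n_eff` into the same
Clopper–Pearson form (`qbeta` accepts non-integer shapes). This is one
defensible choice among several for weighted proportions; it is
deliberately simple, collapses exactly to the unweighted computation when
weights are equal, and is isolated in one function (`weighted_metrics`) so
a design-based variance estimator can replace it without touching
anything else.

The administrative-code baseline treats every in-scope scan as "screening
per codes": its PPV is the gold-screening fraction, its NPV is undefined
(there are no code-negative scans), and sensitivity/specificity are
flagged not meaningful rather than computed. Classifier-vs-baseline
PPV/NPV comparisons use the two-sample proportion chi-squared test with
Yates continuity correction (the `prop.test` default), two-sided; the
correction can be disabled but is on by default to stay conservative at
these sample sizes.

Reports round to whole percent, half-up, matching the presentation
convention of clinical validation studies; underlying values are kept at
full precision and are what the JSON outputs carry.

## The synthetic order generator

`simulate_orders` exists so the classifier and validator can be exercised
end to end with no clinical data. Each order draws a true indication from
a configured mixture — screening, diagnostic, surveillance, uninformative
— and fills its text from small, human-readable template pools: screening
templates always carry a screening term, diagnostic templates a symptom
term, surveillance templates a Fleischner variant, uninformative templates
no term from any set. Gold labels come from the generating indication,
never from the generated text, so the two noise mechanisms genuinely
decouple text from truth:

* with probability ε₁ (`misleading_screening_rate`, default 0.05) a truly
  diagnostic order's text is replaced by screening-only language — the
  false-positive mechanism, mirroring orders whose symptom lives in the
  chart but whose order text says "lung cancer screening";
* with probability ε₂ (`misleading_symptom_rate`, default 0.03) a truly
  screening order also mentions a symptom — the false-negative mechanism:
  the veto then fires.

Under the exclude-unable policy this yields closed-form expectations the
tests check against: sensitivity 1 − ε₂, and
PPV = p₁(1−ε₂) / (p₁(1−ε₂) + p₂ε₁) for screening/diagnostic mixture
weights p₁, p₂. The default conditions — n = 2000 orders, mixture
(0.5, 0.3, 0.1, 0.1), the ε values above, 5% out-of-scope rate, a 0.7
coin toward non-screening for uninformative gold labels (most
unclassifiable scans are non-screening in practice), lognormal(0, 0.5)
sampling weights — were fixed once as a realistic desk-scale image of a
screening-heavy order stream and are not tuned thereafter. The generator
is a pure function of its config: same seed, byte-identical output, and it
restores the caller's RNG state.

What the generator does **not** emulate: real misspellings and
abbreviation soup beyond the template text, order-text length variation,
correlated orders within a patient over time, site-specific procedure-name
catalogs, and drift in ordering vocabulary. Passing the recovery tests
therefore shows the pipeline is internally consistent — the classifier
recovers exactly the signal the generator planted, at the configured
rates — not that these accuracy figures transfer to any particular health
system's extracts. Transfer requires validation against chart review in
the target system; the validation module is the tooling for exactly that.

## Numerical and degenerate-input choices

* Matching is deterministic; duplicate spans from overlapping term sets
  are dropped (first term wins at a span), and hits are reported
  left-to-right.
* `build_contingency` errors when a classified scan lacks a gold label
  (listing the scan ids), drops `excluded` calls and `unknown` gold with
  counts, and accepts empty input (all-zero table).
* `clopper_pearson` rejects k > n, n = 0, and confidence levels outside
  (0, 1); weighted metrics reject non-positive weights naming the scans.
* Dates are ISO 8601 calendar dates with no timezone semantics; files are
  UTF-8.
* The CLI exits 0/1/2 (success / runtime or validation error / usage
  error) and never writes partial output past an error.

## Problem sizes in the shipped tests

The test suite validates the metric layer against the published validation
contingency tables directly (n = 147 and n = 335 scans expanded to
per-scan records), runs property checks on a few hundred randomized small
orders per invariant against brute-force oracles, checks 95%
Clopper–Pearson coverage over 2000 simulated binomial draws at n = 50,
p = 0.8, and runs the end-to-end recovery at the generator's default
n = 2000. These sizes were chosen as the smallest at which the stochastic
checks are stable to within their stated tolerances (3 Monte-Carlo
percentage points for the recovery checks).

## Known limitations

* The default diagnostic list is a stand-in seed list, not an exhaustively
  validated vocabulary; accuracy on real extracts depends on extending it.
* Negation handling is limited to the four exception phrases; there is no
  general negation parser, stemming, or spell-correction.
* The prefix reading of `scr-` is an interpretation; a raw-substring
  reading would also match mid-word occurrences and can be obtained by
  editing the lexicon if a target system's text warrants it.
* Weighted intervals use an effective-sample-size approximation, not a
  design-based variance estimator for the specific survey design.
* One-scan-at-a-time classification is O(fields × terms) per order in
  plain R; the design favors auditability over throughput, and desk-scale
  batches (thousands of orders) run in seconds.
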