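# lcscreen

Identify lung cancer screening (LCS) exams from the text of radiology
orders, and quantify how well the identification works.

## The problem

Lung cancer screening is an annual low-dose chest CT (LDCT) offered to
asymptomatic, high-risk patients. Observational research on screening —
uptake, adherence, complication rates, cancer detection — needs to know
which chest CTs were *ordered as screening*. Administrative billing codes
are a poor guide: the generic chest-CT code (CPT 71250) is also the code
the American College of Radiology requires for interval screening LDCTs,
and even the LCS-specific codes (G0297, S8023, 71271) are routinely
attached to scans ordered for a cough, a lung nodule under surveillance, or
other diagnostic indications. Counting those scans as "screening" inflates
estimated screening rates and biases estimates of screening's harms and
benefits, because symptomatic patients have a higher pre-test probability
of disease. Manual chart review resolves the indication but does not scale.

`lcscreen` implements a rule-based classifier over the three text fields a
radiology order carries in VA-style data — the standardized procedure name
and the two clinician-editable free-text fields (Reason for Exam, Clinical
History) — together with the validation machinery needed to measure its
diagnostic accuracy against chart-review gold labels. It is aimed at
clinical informaticists and health-services researchers building screening
cohorts from electronic health record extracts.

## The algorithm

Each order is mapped to one of four calls:

1. **Scope filter** — orders are `excluded` when no CPT code is in the
   chest-CT scope set {71250, G0297, S8023, 71271}, when the encounter is
   ED or inpatient (typically symptom-prompted), or when the text carries
   an imported-exam marker ("Exam imported from outside", "Imported
   study").
2. **Screening terms** (`low dose`, `ldct`, `lcs`, `scr-` as a token
   prefix) are sought in all three text fields, after masking exception
   phrases in which screening language is misleading boilerplate ("Is this
   procedure to screen for malignancy?", "HCC screening.", ...).
3. **Diagnostic terms** (cough, hemoptysis, weight loss, ...) and
   **Fleischner terms** (nodule-surveillance guideline spellings) are
   sought in the two free-text fields.
4. **Decision**: any diagnostic or Fleischner hit → `non_screening` (a
   hard veto, even when screening language co-occurs); otherwise any
   screening hit → `screening`; otherwise `unable` (no term evidence
   either way — handled downstream by an explicit analysis policy).

Validation crosses calls with gold labels into a 2×2 table and reports
sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp) and NPV
tn/(tn+fn), each with an exact Clopper–Pearson interval
(qbeta(α/2, k, n−k+1), qbeta(1−α/2, k+1, n−k)); survey-weighted variants
use ratios of weight sums with a Kish effective sample size
(Σw)²/Σw². PPV/NPV are compared against the code-only baseline (every
in-scope scan counted as screening) with the Yates-corrected two-proportion
chi-squared test.

A synthetic order generator emulates the input stream — a configurable
mixture of screening / diagnostic / nodule-surveillance / uninformative
indications with misleading-text noise in both directions — so the whole
pipeline is testable end to end without clinical data.

## Worked example

```r
library(lcscreen)
lex    <- lcs_lexicon()
orders <- simulate_orders(sim_config(n_orders = 500, seed = 20), lex)
calls  <- classify_orders(orders, lex)
summary(calls)$by_call
#>      excluded     screening non_screening        unable
#>            26           231           188            55

tab <- build_contingency(calls, orders, policy = "exclude_unable")
accuracy_metrics(tab)
#> <lcs_accuracy> 95% CI, policy: exclude_unable
#>   sensitivity   97% (94-99%)  [218/225]
#>   specificity   93% (89-96%)  [181/194]
#>   ppv           94% (91-97%)  [218/231]
#>   npv           96% (92-98%)  [181/188]

cpt_baseline(orders$gold_label[calls$call != "excluded"])
#> <lcs_accuracy> 95% CI, policy: all_in_scope_called_screening
#>   sensitivity  not meaningful for this comparison
#>   specificity  not meaningful for this comparison
#>   ppv           51% (47-56%)  [243/474]
#>   npv          undefined (zero denominator)
```

Reading: of 500 simulated orders, 26 fall out of scope; among classifiable
in-scope scans the classifier finds screening scans with 97% sensitivity
and calls of "screening" are right 94% of the time, while under code-only
ascertainment barely half of the scans labeled screening truly are — the
gap the classifier exists to close. Single orders can be audited:

```r
classify_order(data.frame(scan_id = "EX1", patient_id = "P1",
  exam_date = "2021-03-04", cpt_codes = "71250", setting = "outpatient",
  procedure_name = "CT CHEST WO CONTRAST",
  reason_for_exam = "low dose ct; cough 6 weeks", clinical_history = ""),
  lex)
#> <lcs_call> EX1 -> non_screening
#>   screening_hits : low dose
#>   diagnostic_hits : cough
```

A command-line interface wraps the same functions
(`inst/cli/lcscreen.R classify|validate|simulate`); every run writes a JSON
manifest recording inputs, lexicon version, policy flags, seed and package
version.

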