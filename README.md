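# oddsrules

Interpretable in-hospital mortality risk estimation by odds-ratio
associative classification.

## The problem

In emergency and critical care, an early, objective estimate of a
patient's in-hospital mortality risk informs triage, resource
allocation, and the timing of palliative conversations. Machine-learning
risk scores exist, but providers need to see *why* a patient is flagged,
and critical-care records hold hundreds of thousands of heterogeneous
categorical variables (diagnoses, prescriptions, procedures, wards,
demographics) that defeat most interpretable learners.

`oddsrules` implements an associative-classification approach built for
exactly this setting. Every clinical case is reduced to an *itemset*:
the set of (variable type, code) pairs recorded during the stay, with a
binary died/survived outcome. The method mines one rule per item,

&nbsp;&nbsp;&nbsp;&nbsp;*item &rArr; in-hospital mortality*,

scored not by the classical support/confidence metrics (which hide rare
but dangerous conditions) but by the **odds ratio** of the item's 2×2
contingency table against the outcome:

    OR = (a·d) / (b·c)

where *a*/*b* count cases with the item that died/survived and *c*/*d*
the same for cases without the item. Tables with a zero cell (OR of 0 or
&infin;) are discarded. Each surviving OR is tested against 1 with the
normal approximation of the log odds ratio (Woolf standard error
`sqrt(1/a + 1/b + 1/c + 1/d)`, two-sided p); only rules with
`p < p_max` are kept, optionally with Bonferroni correction
(`p_max / #tests`). The special setting `p_max = 0` keeps only rules
whose p-value underflows to exactly zero — the strictest filter.

A new case *p* is scored by the arithmetic mean OR<sub>p</sub> of the
rules that apply to it, and classified by a decision boundary &delta;:

    f(p) = high risk   if OR_p >= delta
           low  risk   if OR_p <  delta

&delta; is calibrated by maximizing the Youden index
(sensitivity + specificity − 1) on a training ROC curve. Two model
classes are supported: a **minimal** model over the five
patient-reportable admission-time demographics (gender, ethnicity,
insurance type, language, marital status) and a **full** model over all
ten variable types.

Because access to real critical-care databases is credentialed, the
package ships a synthetic EHR population generator with *planted*
per-item odds ratios (`mimicLikeConfig()`, `generatePopulation()`), so
mining, prediction, and the whole evaluation protocol are testable end
to end.

## Worked example

The bundled fixtures reproduce a fictional emergency-department
patient and two illustrative rule models transcribed from a published
rule table:

```r
library(oddsrules)

patient <- exampleCase()        # 9 items, outcome unknown
minimal <- exampleRuleModel("minimal")  # 13 rules, boundary 1.015

applyingRules(minimal, patient)[, c("variableType", "code", "oddsRatio")]
#>     variableType                   code oddsRatio
#> 1      ethnicity Black/African American      0.58
#> 2         gender                 Female      0.80
#> 3 insurance_type               Medicaid      0.57
#> 4       language                English      0.73
#> 5 marital_status                 Single      0.50

classifyCases(minimal, patient)
#>      caseId score nApplyingRules    label
#> 1 patient_1 0.636              5 low-risk
```

On admission-time information alone the patient's mean OR is 0.636,
below the minimal boundary 1.015: low risk. Once the clinical picture
develops (acidosis, anuria/oliguria, sodium bicarbonate, furosemide),
the full model's nine applying rules lift the mean OR above its
boundary 5.306:

```r
full <- exampleRuleModel("full")
classifyCases(full, patient)
#>      caseId    score nApplyingRules     label
#> 1 patient_1 5.327778              9 high-risk
```

A complete mining/evaluation run on synthetic data:

```r
pop   <- generatePopulation(mimicLikeConfig("small"), seed = 1)
model <- mineRules(pop, pMax = 0.05, bonferroni = TRUE)
cells <- runGrid(pop, repetitions = 10, seed = 1)   # 26 configs x 10 splits
aggregateGrid(cells)
```

The same operations are available from a shell through the thin CLI
wrapper (`inst/scripts/oddsrules-cli.R`) with subcommands
`simulate | mine | predict | evaluate | report`.

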