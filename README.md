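# triagecc

Diagnostic accuracy of prehospital major-trauma triage under a case-cohort
design.

English trauma networks route the most seriously injured patients past the
nearest hospital to a Major Trauma Centre (MTC), guided by step-wise field
triage tools and crew judgement. Evaluating how well those decisions work is
awkward: major trauma is rare (~3% of conveyed injured patients), so accuracy
studies enrich a random *sub-cohort* of all-comers with *every*
registry-identified case — a case-cohort design — and analyse it unweighted.
`triagecc` provides that whole analysis chain as a tested R package, for
trauma-system researchers and methodologists who want to reproduce, stress or
extend this class of study without access to the underlying registry data:

- **`synthetic cohorts`** — `generate_parent_cohort()` simulates an
  elderly-skewed blunt-trauma population (ground-level falls dominate) with
  serial vital signs, AIS-coded injuries, urgent interventions, and a
  provider pre-alert decision whose sensitivity/specificity and age trend are
  configurable; `draw_case_cohort_sample()` and `link_records()` apply the
  sampling design and deterministic report-form-number linkage.
- **`triage rules`** — declarative YAML/JSON tool specifications (steps 1–4:
  physiology and anatomy mandatory, mechanism and special circumstances
  discretionary) evaluated cumulatively by `evaluate_tool()`, with
  first-recorded-value and sustained (two consecutive measurements)
  physiology semantics and full evidence traces.
- **`reference standards`** — `classify_reference_standards()` scores each
  record against a four-domain consensus definition of benefit from expedited
  MTC care, plus ISS ≥ 16 (`compute_iss()` implements the Injury Severity
  Score: sum of squares of the highest AIS severity in the three most
  severely injured of six body regions), urgent interventions alone, and the
  consensus standard without open fractures.
- **`accuracy estimation`** — sensitivity `TP/(TP+FN)`, specificity
  `TN/(FP+TN)`, likelihood ratios `LR+ = sens/(1−spec)`,
  `LR− = (1−sens)/spec` with Wilson/Wald and log-method confidence
  intervals, sub-cohort prevalence, post-test probabilities via Bayes on the
  odds scale, stratified and cumulative-step analyses, and broom-style
  `tidy()`/`glance()` methods.
- **`pipeline`** — `run_pipeline()` chains
  simulate → link → sample → filter → classify → triage → estimate → report
  into a reproducible bundle of tidy CSVs, plots and a hashed JSON manifest.

## Worked example

The pooled observed triage decisions of four ambulance services, entered as a
2×2 table (all reference-positive cases against sub-cohort negatives):

```r
library(triagecc)

est <- estimate_accuracy(
  two_by_two(tp = 446, fp = 95, tn = 1703, fn = 513, design = "case_cohort"))
est
#> Diagnostic accuracy (n = 2757, case_cohort design, wilson 95% CI)
#>   sensitivity: 0.47 (0.43-0.50)
#>   specificity: 0.95 (0.94-0.96)
#>   LR+:         8.80 (7.16-10.83)
#>   LR-:         0.56 (0.53-0.60)
```

Fewer than half of the patients who truly benefit from MTC care are
pre-alerted there (sensitivity 0.47), but very few others are (specificity
0.95). Combining the likelihood ratios with the sub-cohort prevalence turns
these into patient-level statements:

```r
prev <- estimate_prevalence(54, n = 1722)   # 3.1% (95% CI 2.3-4.0)
posttest_probability(prev$prevalence, est$lr_pos)      # 0.22
1 - posttest_probability(prev$prevalence, est$lr_neg)  # 0.98
```

A positive triage decision raises the probability of major trauma from 3.1%
to 22%; after a negative decision there is a 98% chance the patient does not
have major trauma. Do *not* read predictive values straight off a
case-cohort table — `predictive_values()` warns, because case enrichment
inflates them.

A full synthetic study, end to end:

```r
cfg <- run_config(
  population = population_config(n_incidents = 20000, seed = 1),
  subcohort_size = 2000, seed = 1, output_dir = "run1")
res <- run_pipeline(cfg)
format_accuracy(res$decision_accuracy_overall)   # overall decision accuracy
res$tool_step_accuracy                           # cumulative steps, per tool
plot_step_roc(res$tool_step_accuracy)
```

The bundled example tools (`example_tools()`) are editable placeholders with
the structure of the deployed service checklists; real evaluations should
supply the services' own specification documents.

## Package layout

| Area | Entry points |
|---|---|
| Synthetic cohorts | `population_config()`, `generate_parent_cohort()`, `apply_complete_case_filter()` |
| Sampling & linkage | `draw_case_cohort_sample()`, `link_records()` |
| Triage tools | `read_triage_tool()`, `evaluate_tool()`, `evaluate_tool_cumulative()` |
| Reference standards | `reference_standard_config()`, `classify_reference_standards()`, `compute_iss()` |
| Estimation | `estimate_accuracy()`, `estimate_prevalence()`, `posttest_probability()`, `stratified_accuracy()`, `cumulative_step_series()` |
| Reporting | `run_pipeline()`, `report_from_counts()`, `plot_step_roc()`, `plot_age_accuracy()` |

See the methods vignette (`vignettes/triage-accuracy-methods.Rmd`) for the
statistical model, generator assumptions and design decisions.
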