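---
title: "Methods: prehospital triage accuracy under a case-cohort design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prehospital triage accuracy under a case-cohort design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triagecc)
```

## The problem

When an ambulance crew attends an injured patient they must decide, with a
step-wise triage tool and their own judgement, whether to bypass the nearest
hospital and pre-alert a Major Trauma Centre (MTC). Both error directions
are costly: under-triage (a false negative) delays definitive care for a
seriously injured patient; over-triage (a false positive) floods MTCs and
removes ambulances from their patch. Because major trauma is rare among
conveyed injured patients (~3%), a simple random sample large enough to pin
down sensitivity would be enormous. The standard remedy is a **case-cohort
design**: take a random sub-cohort of all-comers irrespective of outcome,
add *every* registry-identified reference-standard-positive case, and link
the two sources deterministically on the ambulance report-form number.

`triagecc` implements the whole analysis chain — a calibrated synthetic
cohort generator, a declarative triage-rule engine, configurable reference
standards, and the unweighted case-cohort accuracy estimator — so the design
can be exercised, checked and extended without access to restricted
registry data.

## Estimation model

Let the 2×2 table of an index test against a reference standard have cells
TP, FP, TN, FN. The package computes

- sensitivity $se = TP/(TP+FN)$ and specificity $sp = TN/(FP+TN)$;
- likelihood ratios $LR^+ = se/(1-sp)$ and $LR^- = (1-se)/sp$;
- post-test probabilities by Bayes on the odds scale:
  $odds_{post} = \frac{p}{1-p}\,LR$, $P_{post} = odds_{post}/(1+odds_{post})$,
  with $p$ the pre-test prevalence.

Under the unweighted case-cohort rule (`case_cohort_table()`,
`stratified_accuracy()`, `cumulative_step_series()`), the sensitivity margin
uses **all cases** and the specificity margin **sub-cohort negatives only**;
prevalence (`estimate_prevalence()`) comes from the random sub-cohort alone.
These unweighted estimators are consistent for $se$, $sp$ and $p$ because
case status is exactly the conditioning event of each margin. Row-wise
quantities are *not* estimable this way: predictive values computed directly
from a case-enriched table are inflated, so `predictive_values()` warns on a
`case_cohort` table and the supported route is
`posttest_probability(prevalence, lr)`. On a simple random sample the two
routes agree exactly (this identity is property-tested).

**Confidence intervals.** Proportions default to the Wilson score interval,
with a Wald option (`ci_method = "wald"`); Wilson is preferred for its
behaviour at small counts and extreme proportions. Likelihood-ratio
intervals use the log-transform (Simel) method,
$\exp\{\ln LR \pm z\,\hat\sigma\}$ with
$\hat\sigma^2 = 1/TP - 1/(TP+FN) + 1/FP - 1/(FP+TN)$ for $LR^+$ (cells
swapped accordingly for $LR^-$). When a cell is empty the point estimate is
reported as is (`Inf` is flagged) and a 0.5 continuity correction is applied
to the interval only.

**Rounding.** Published accuracy tables conventionally round half *up* at
two decimals (6.125 → 6.13), whereas base R rounds half to even. All
internal arithmetic keeps full precision; `round_half_up()` is applied only
at presentation time (`format_accuracy()`, printing).

## The triage-rule engine

A tool is an ordered list of steps, each an OR over criteria
(`triage_tool()`, `read_triage_tool()`). Grouped tools have physiology
(step 1) and anatomical injury (step 2) as mandatory steps and mechanism
(step 3) and special circumstances (step 4) as discretionary ones;
ungrouped tools are a single checklist. Evaluation semantics:

- non-sustained physiology criteria compare the **first recorded** value of
  the vital-sign series;
- *sustained* criteria require **two or more consecutive** measurements
  meeting the threshold, read in recording order (timestamps are retained
  in the evidence trace but do not affect the run test); a single
  measurement can never satisfy a sustained criterion;
- comparators are applied exactly as written — strict and inclusive
  thresholds are distinct and measured values are never rounded;
- categorical criteria test set membership of the mechanism class, of
  derived injury-pattern labels (`derive_injury_patterns()`), or of derived
  special circumstances.

The cumulative result at depth $k$ is the OR of steps $1..k$, hence
monotone non-decreasing in $k$; consequently cumulative sensitivity is
non-decreasing and cumulative specificity non-increasing in depth for any
labelled sample — the qualitative pattern any stepped checklist must show.
All criteria are always evaluated (no early exit), and both the
mandatory-only and all-steps verdicts are reported, so sequential and
parallel readings of a tool are available side by side.

Missing data follow a complete-case policy by default: a required variable
that is absent raises an explicit error rather than silently evaluating
false. An optional `criterion_skip` mode instead treats only the affected
criterion as unsatisfied and flags the record.

The four bundled tools are **synthetic placeholders**: they have the
structure of deployed English ambulance-service checklists (three grouped
four-step tools, one ungrouped) populated with conventional field-triage
thresholds (SBP < 90 mmHg, GCS ≤ 13, RR < 10 or > 29 /min, penetrating
torso injury, fall > 1 m, age bands). The deployed variable lists are
service documents; real evaluations must supply them as YAML/JSON files.

## Reference standards

The primary standard is a four-domain consensus definition of benefit from
expedited MTC care: critical interventions, significant individual
injuries, multiple-injury burden, and capacity to benefit. The operational
clinical lists behind the domains are owned by an external consensus
process, so each domain is a configurable predicate
(`reference_standard_config()`); the defaults are deliberately
conventional:

| domain | default predicate |
|---|---|
| critical interventions | any of intubation, thoracostomy, blood transfusion, emergency surgery, interventional radiology |
| significant injury | any AIS ≥ 4; head AIS ≥ 3; open fracture with AIS ≥ 2 |
| multiple injuries | ≥ 2 body regions with maximum AIS ≥ 3 |
| capacity to benefit | age ≥ 65 with any AIS ≥ 3 |

Whether capacity to benefit can hold with no coded injury at all is
genuinely open; the default requires at least one injury
(`require_injury = TRUE`), and the switch is exposed.

Secondary standards: ISS ≥ 16; the critical-interventions domain alone; and
the consensus standard with open-fracture-triggered rules removed. The ISS
(`compute_iss()`) is the sum of squares of the highest AIS severity in the
three most severely injured of the six classic body regions, with the
standard convention that any AIS 6 injury scores 75 (never exercised by the
generator, which draws severities 1–5, but honoured for user-supplied
data). By construction the secondary standards imply the primary one where
the definitions overlap, and this implication lattice is fuzz-tested.

## What the synthetic generator emulates

`population_config()` defaults describe a winter cohort of injured patients
conveyed by four English ambulance services:

- **prevalence** 0.031 of consensus-positive major trauma;
- **ages** from a child/adult/elderly (< 16 / 16–64.9 / ≥ 65 years) mixture
  per status (positives 3.2/51.2/45.6%, negatives 6.6/35.8/57.6%), uniform
  within the child and adult bands and Beta(2,2)-skewed across 65–103 so the
  negative stratum median lands near 73 years and the positive near 61;
- **mechanisms** over eleven classes, negatives dominated by ground-level
  falls (70.9%); mode of injury is derived (penetrating iff stabbing or
  gunshot);
- **serial vitals**: 1–4 measurements per record (weights
  0.15/0.35/0.30/0.20); first values from truncated normals per status —
  SBP 137 vs 142 mmHg, RR 20 vs 18 /min, SpO2 medians 97 vs 97% — and GCS
  from a deficit distribution concentrated at 15; later values follow a
  bounded random walk (SDs 8 mmHg, 2 /min, 1.5%), which is what makes
  sustained criteria non-trivial;
- **injuries**: per-region Bernoulli marginals with per-status severity
  weights calibrated so the positive ISS distribution has median 18 and IQR
  13–25; 30.8% of positives receive an urgent intervention; positives'
  injury sets are redrawn (up to 25 times, then an urgent intervention is
  added) until the default consensus standard is satisfied, so rule-based
  classification agrees with generative status;
- **provider behaviour**: pre-alert probability logistic in true status and
  age. The slopes (default −0.032/yr on the positive logit, −0.02/yr on the
  negative false-positive logit) encode the observed spectrum effect —
  sensitivity falls and specificity rises with age — and the intercepts are
  solved by `uniroot()` on the realised cohort so the whole-sample
  expectations hit the configured sensitivity/specificity targets exactly,
  whatever the age distribution;
- **missingness** only in the report-form identifier (5%) and in whole
  vital-sign series (3%), keeping the complete-case rate above 90%.

A single master seed drives everything; stage-level child seeds are derived
by fixed offsets, so cohorts, samples and linkage reports are byte-identical
under a repeated configuration.

**What it does not emulate:** free-text clinical narratives, probabilistic
manual matching of unlinked cases, per-service population differences
(services share one set of generator parameters, since only their accuracy
— not their case mix — is configured to differ), registry submission rules,
or informative missingness. Passing tests on this generator therefore
demonstrate the *estimators and engine* are correct under the design, not
that any particular real-world service performs at the simulated level.

## Numerical and design choices

- **Degenerate inputs.** A requested prevalence of 0 or 1 is a
  configuration error (a cohort with no positives or no negatives cannot
  support accuracy estimation); empty 2×2 margins raise errors naming the
  margin; an empty sub-cohort refuses a prevalence estimate; strata must
  strictly partition the age axis.
- **Linkage** is exact-key only: missing keys and keys duplicated in either
  source are counted unmatched (ambiguous), never guessed.
- **Age bins** default to `<16` then ten-year adult bands ending at `90+`,
  configurable, since "adult age deciles" admits several readings.
- **Sub-cohort overlap**: positives drawn into the sub-cohort are retained
  once with both provenance flags, so the analysis set has no duplicates
  while both margins stay correct.
- **Problem sizes.** The test suite exercises the full chain at
  n = 20,000 (step-monotonicity across every tool) and n = 50,000
  (parameter recovery and population calibration), with 1,000-record fuzz
  corpora against naive brute-force oracles for the rule engine and an
  exhaustive enumeration (all injury multisets of up to four injuries,
  severities 1–5, six regions) for the ISS. These sizes give Monte-Carlo
  error comfortably below the tolerances being checked while keeping a full
  run in minutes.
- The whole-sample operating point of the simulated provider is recovered
  within binomial Monte-Carlo bounds at n = 50,000, and the configured age
  trend is recovered monotonically across broad age bins; both checks run
  in the acceptance suite on every test run.

## Known limitations

- The unweighted estimator is the point of the design; weighted
  (Prentice/Barlow-style) case-cohort estimators are out of scope.
- Reference-standard misclassification, imperfect linkage bias and
  informative missingness are not modelled; the generator's linkage
  failures are missing-completely-at-random.
- The bundled tool thresholds and consensus-domain defaults are documented
  placeholders, and per-service results under them should not be read as
  statements about the corresponding real services.
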