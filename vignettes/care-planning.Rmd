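---
title: "Rule-based care planning and real-time insulin advice for type 1 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based care planning and real-time insulin advice for type 1 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1dplan)
```

## The clinical model

People with type 1 diabetes produce no insulin and must replace it
exogenously. A care plan balances the things that raise blood glucose
(food, illness, stress) against the things that lower it (insulin,
exercise). `t1dplan` implements a deterministic, auditable version of the
rule- and formula-based planning knowledge found in consensus clinical
practice guidelines (CPGs): every recommendation is a pure function of the
coded patient profile, the loaded knowledge base, and — for real-time
advice — the incoming observations. The system only *proposes*: plans are
created in `draft` status and a physician records approval.

### Insulin sub-plan

The starting total daily dose is weight-based,

$$\mathrm{TDD} = 0.6 \cdot W \;\; \mathrm{U/day},$$

for both regimen families. Two regimens are supported:

* **Twice-daily fixed (DF)**: morning dose $\mathrm{MD} = \tfrac23
  \mathrm{TDD}$ and evening dose $\mathrm{ED} = \tfrac13 \mathrm{TDD}$;
  the morning dose splits 2/3 intermediate-acting (e.g. NPH) and 1/3
  short-acting (regular), the evening dose splits in half. The four
  components always sum exactly to TDD before rounding. The patient keeps
  a fixed diet and activity pattern, so the plan marks the activity level
  as frozen.
* **Intensive insulin therapy (IIT, basal-bolus)**: basal dose
  $\mathrm{BA} = f \cdot \mathrm{TDD}$ with $f \in \{0.3, 0.4, 0.5,
  0.6\}$ and bolus $\mathrm{BO} = (1-f)\,\mathrm{TDD}$ split into three
  equal pre-meal shots. The literature does not give a crisp rule for
  choosing $f$, so the package defaults to 0.5 (the value most CPGs use)
  and exposes the argument rather than inventing selection logic.

Pregnant patients and children are always planned on IIT; other patients
get their stated preference. Product selection walks the knowledge base
catalog in preference-rank order and skips any insulin that is drug-drug
contradicted with a current medication or drug-disease contradicted with
a current condition; if every product of a class is contradicted the
planner fails loudly with the reasons rather than guessing.

### Diet sub-plan (medical nutrition therapy)

The five steps: (1) basal metabolic rate from the revised Harris-Benedict
equations (the metric male height coefficient is 5.003 kcal/cm — the
value of the standard revised equation); (2) maintenance calories
$\mathrm{MC} = \mathrm{AL} \cdot \mathrm{BMR}$ using the five-level
activity multiplier table (1.2, 1.375, 1.55, 1.725, 1.9); (3) the ideal
weight range from the healthy BMI band 18.5–25 kg/m²; (4) daily calories
$\mathrm{CpD}$ adjusted by 7700 kcal per kg of weight to gain or lose,
spread over an adjustment period `d` (default 90 days, the plan
maintenance cadence); and (5) carbohydrate grams $\mathrm{CpD}/4$ split
30/35/35 % over breakfast/lunch/dinner, with the same shares applied to
calories. The $\mathrm{CpD}/4$ rule deliberately treats every daily
calorie as carbohydrate (4 kcal/g); that is the encoded guideline
convention, implemented verbatim even though it ignores protein and fat
calories. Weight goals use the nearest healthy endpoint (LIW when
underweight, HIW when overweight), the guideline stating only the
inequalities. A reduction that would drive CpD non-positive raises a
"period too short" error instead of emitting a starvation diet.

### Exercise and education sub-plans

Exercise eligibility is a disjunctive gate over the knowledge base's
forbidding conditions (hypertension, dyslipidemia, preproliferative
retinopathy, nephropathy, cigarette smoking), plus pregnancy-specific
triggers (BMI < 12 kg/m², preeclampsia and other listed
contraindications). The source rule also mentions age > 30; because the
rule body conjoins it with the comorbidity list, the package records age
as an aggravating reason but never bans on age alone — a deliberate
reading of an ambiguous rule, chosen so that a healthy 45-year-old is not
excluded from exercise. Forbidden exercises are the union of
disease-exercise contradictions (foot ulcers → jogging, cataracts →
cycling, severe nonproliferative retinopathy → jumping/jarring/
breath-holding); recommendations are the patient's preferences minus that
set, falling back to a default set. Components carry compendium MET
values and age-banded default frequency/duration (3–5 sessions/week,
20–30 min, generic CPG practice, config-overridable).

Education plans pick learning styles from an (age category, education
level) table — only three rows of which are fixed by the source rules
(highly educated adults: visual + reading; children: games + visual;
older low-education adults: auditory + visual); the remaining rows are
shipped defaults. IIT patients must at minimum cover glucose monitoring,
insulin management and diet management; complications, a
hypo/hyperglycemia history, and an active exercise plan add topics.
Course assignment is a deterministic catalog join over (topic, style)
pairs with deduplication.

### Real-time monitoring

For IIT patients the two evaluation factors are

$$\mathrm{ISF} = \frac{1800}{\mathrm{TDD}} \;\mathrm{mg/dL/U}
  \quad\text{(100 rule for mmol/L)}, \qquad
  \mathrm{ICR} = \frac{500}{\mathrm{TDD}} \;\mathrm{g/U}
  \quad\text{(300 rule when TDD} < 10\,\mathrm{U)}.$$

Mealtime advice computes $\mathrm{DBG} = \mathrm{CBG} - \mathrm{PBG}$,
correction units $N_1 = \mathrm{DBG}/\mathrm{ISF}$, carb-cover units
$N_2 = \mathrm{MC}/\mathrm{ICR}$ and the bolus $\mathrm{BD} = N_1 + N_2$.
Positive BD is injected (displayed to the nearest 0.5 U, exact value
retained for chained computation); zero skips the bolus; negative BD
means the patient should eat carbohydrate. The source only says "some
more carbs"; the package quantifies it as $(-\mathrm{BD}) \cdot
\mathrm{ICR}$ grams — the carb mass the insulin deficit covers — and
documents this as a derived rule.

Exercise within three hours after a meal reduces the bolus by the insulin
equivalent of the burned calories, $\mathrm{BD} = N_1 + N_2 -
(\mathrm{BC}/4)/\mathrm{ICR}$ with $\mathrm{BC} = \mathrm{MET} \cdot W
\cdot h$. Exercise is gated: above 250 mg/dL, below 80 mg/dL, or with
ketoacidosis no offset is applied and the advice is flagged. Away from
meals, overweight patients get the insulin equivalent subtracted from
$N_1$; underweight and normal-weight patients are told to eat
$\mathrm{BC}/4$ grams *and* have the equivalent units added to $N_1$ —
arithmetically surprising, but that is what the source prescribes, and it
is implemented verbatim rather than rationalized.

The correction-band table is printed in the source for the goal range
100–150 mg/dL only; the package totalizes it by anchoring 50 mg/dL bands
at the goal's upper bound (+1 per band, capped at +4) with −1 below
70 mg/dL. The zone between 70 mg/dL and the goal floor is unspecified in
the source; the package returns the in-goal behavior (0) there.

**Pattern management.** Basal and bolus doses are titrated only on
persistent evidence: a slot must be out of goal on the same side on three
consecutive days. Single excursions never trigger. The slot-to-dose
mapping is fixed (before-lunch ↔ before-breakfast bolus, before-dinner ↔
before-lunch bolus, before-bedtime ↔ before-dinner bolus,
before-breakfast ↔ bedtime basal) and adjustments are bounded to 10–20 %
of the planned dose, defaulting to the minimum 10 %. Logs longer than
three days are scanned window-by-window and deduplicated per slot,
keeping the most recent finding ("at least three days" is interpreted as
scanning every three-day window).

## Numerical choices and degenerate inputs

* Glucose units convert with the fixed factor 18.0182 mg/dL per mmol/L;
  the conversion is self-inverse to 1e-9 relative tolerance, and advice
  differs by less than 0.05 U between unit systems for the same
  physiological state.
* Age bands: child ≤ 12, adolescent 13–18, adult 19–55, oldAdult > 55.
  Only the adult band (19–55) and a child anchor (< 10) are fixed by the
  source; the remaining cut-offs are a package convention, configurable
  via the knowledge base.
* Plan doses round to whole units for presentation, advice to 0.5 U;
  exact values are always retained in the objects.
* Zero TDD, zero meal carbs, and zero exercise duration are all valid
  degenerate inputs and propagate linearly; non-positive weight, height
  or TDD raise validation errors.
* Goal templates for strata other than pregnant adults are shipped
  defaults in the style of consensus guidelines, clearly marked
  synthetic in the config, because the source prints only the
  pregnant-adult row.

## The synthetic data generator

`scenario()` fixes demographic ranges, a regimen mix, glucose sensor
noise (Gaussian, default sd 10 mg/dL) and optional pattern injections;
every artifact is a pure function of (scenario, seed, index). Glucose
logs draw per-slot baselines inside the goal range; injected slots are
anchored at the goal midpoint so that an injection of magnitude above the
goal half-width plus three noise standard deviations is detectable with
high probability, and noise-free uninjected logs never trigger a
finding. The generator emulates self-monitoring logs and heterogeneous
demographics, *not* physiology: there is no insulin-glucose dynamics, no
meal absorption, no circadian structure. Passing tests therefore
demonstrate the correctness of the rule and formula engine on data of the
documented shape, not clinical performance on real sensor traces.

The worked-example patient ships with weight $50/0.6$ kg so the
weight-based dose rule lands exactly on TDD = 50 U, making the printed
real-time example reproducible end to end.

## A worked example

```{r example}
kb <- load_knowledge_base()
patient <- worked_example_profile()
plan <- build_care_plan(patient, kb)
plan$regimen

advise_bolus(quantity(210, "mg/dL"), quantity(120, "mg/dL"),
             meal_carbs_g = 60, tdd = plan$regimen$tdd)

findings <- detect_patterns(table_log_fixture(), c(70, 140))
str(findings[[1]], max.level = 1)
adjust_doses(plan$regimen, findings)$doses[[1]]$units
```

## Problem sizes used in the test suite

The property suites run at sizes chosen to make the checks convincing
while keeping the suite fast on one CPU: dose conservation over 10^4
random TDDs, pattern-detector equivalence with a brute-force window scan
over 1000 randomized logs, unit-invariance of advice over 200 random
states, and injected-pattern recovery over 200 seeded logs.

## Known limitations

* The shipped contradiction and course catalogs are illustrative, not a
  clinical registry; correctness is defined relative to the loaded
  knowledge base, which deployments are expected to replace.
* Premixed insulins (70/30, 50/50) and between-meal snacks are out of
  scope, as are emergency-treatment procedures (dangerous glucose levels
  are only flagged via `classify_glucose_danger()`).
* FHIR serialization is a profiled "lite" subset: resourceType/id plus
  the element subset this tool exchanges, with fixed status values
  (`Observation.status = "final"`, confirmed conditions); no narrative,
  meta, or server semantics.
* The underweight exercise-away-from-meals branch adds both carbs and
  insulin by construction of the source rule; clinical review before use
  is assumed.
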