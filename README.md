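# t1dplan

Rule-based care-plan construction and real-time insulin advice for type 1
diabetes, as a deterministic, testable R library with a thin command-line
front end.

People with type 1 diabetes (T1D) inject insulin several times a day and
must continuously reconcile glucose readings, meals and exercise. This
package implements the planning and monitoring knowledge of consensus
clinical practice guidelines as pure functions: given a coded patient
profile and a configurable knowledge base it builds a complete
personalized care plan (insulin regimen, diet, exercise, education) and,
for basal-bolus patients, gives auditable mealtime bolus advice and
multi-day glucose pattern management. It is aimed at clinical-informatics
researchers and decision-support developers who need the computations to
be reproducible and inspectable; the system proposes, a physician
approves.

## The model in brief

* **Total daily dose** TDD = 0.6 · weight (U/day), for any regimen.
* **Twice-daily fixed regimen**: MD = ⅔ TDD, ED = ⅓ TDD; the morning dose
  splits ⅔ intermediate- / ⅓ short-acting, the evening dose in half.
* **Basal-bolus (IIT)**: BA = f · TDD with f ∈ {0.3, 0.4, 0.5, 0.6}
  (default 0.5); BO = (1−f) · TDD in three equal pre-meal shots.
* **Diet**: Harris-Benedict BMR × activity level (1.2–1.9) gives
  maintenance calories; the healthy BMI band 18.5–25 gives the ideal
  weight range; 7700 kcal per kg of weight change over an adjustment
  period d sets calories/day; carbs = CpD/4 g split 30/35/35 % over the
  three meals.
* **Real-time advice**: ISF = 1800/TDD (mg/dL; 100 rule for mmol/L),
  ICR = 500/TDD (300 rule below 10 U); DBG = CBG − PBG,
  N1 = DBG/ISF, N2 = carbs/ICR, bolus BD = N1 + N2, minus
  (BC/4)/ICR when exercising after the meal (BC = MET · kg · h).
* **Pattern management**: a slot out of goal on the same side three
  consecutive days titrates the mapped dose by 10–20 % (before-breakfast
  highs raise the bedtime basal, etc.); single excursions never do.

Profiles, observation streams and plans are exchanged as FHIR-style JSON
bundles; the knowledge base (insulin catalog, contradiction maps, MET
table, goal templates, course catalog) is a YAML/JSON config with shipped
illustrative defaults.

## Worked example

```r
library(t1dplan)
kb <- load_knowledge_base()
patient <- worked_example_profile()   # 83.33 kg adult on basal-bolus
plan <- build_care_plan(patient, kb)
plan$regimen
#> <insulin regimen> IIT, TDD 50.0 U/day
#>   bedtime          detemir       25.0 U (basal)
#>   before_breakfast aspart         8.3 U (bolus)
#>   before_lunch     aspart         8.3 U (bolus)
#>   before_dinner    aspart         8.3 U (bolus)

advise_bolus(quantity(210, "mg/dL"), quantity(120, "mg/dL"),
             meal_carbs_g = 60, tdd = plan$regimen$tdd)
#> <bolus advice> DBG 90.0 | N1 2.50 U | N2 6.00 U | BD 8.50 U -> inject 8.5 U
```

The advice reads: the patient is 90 mg/dL above the pre-meal goal, which
needs 2.5 correction units at ISF 36 mg/dL/U; the 60 g meal needs 6 units
at ICR 10 g/U; inject 8.5 U before eating.

Pattern management over a three-day log (goal 70–140 mg/dL):

```r
findings <- detect_patterns(table_log_fixture(), c(70, 140))
findings[[1]]$affected_dose
#> [1] "bedtime_basal"
adjust_doses(plan$regimen, findings)$doses[[1]]$units
#> [1] 27.5     # the 25 U bedtime basal raised by 10%
```

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/t1dplan plan    --patient patient.json --out plan.json
Rscript inst/cli/t1dplan advise  --patient patient.json --cbg 210 --carbs 60
Rscript inst/cli/t1dplan monitor --patient patient.json --log log.json
Rscript inst/cli/t1dplan synth   --out fixtures --seed 1
```

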