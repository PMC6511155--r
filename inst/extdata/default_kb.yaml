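# Default knowledge catalogs for the t1dplan decision support engine.
# The contradiction lists are illustrative, mirroring the printed guideline
# examples; real deployments load a site-specific catalog. Correctness of
# the planners is defined relative to the loaded knowledge base.

age_bands:
  child_max: 12
  adolescent_max: 18
  adult_max: 55

activity_levels:
  sedentary: 1.2
  lightly_active: 1.375
  moderately_active: 1.55
  very_active: 1.725
  extra_active: 1.9

insulin_catalog:
  - code: detemir
    display: insulin detemir (Levemir)
    action_class: long
    preference_rank: 1
  - code: glargine
    display: insulin glargine (Lantus)
    action_class: long
    preference_rank: 2
  - code: aspart
    display: insulin aspart (Novolog)
    action_class: rapid
    preference_rank: 1
  - code: lispro
    display: insulin lispro (Humalog)
    action_class: rapid
    preference_rank: 2
  - code: nph
    display: NPH insulin
    action_class: intermediate
    preference_rank: 1
  - code: regular
    display: regular insulin
    action_class: short
    preference_rank: 1

# Stored once per unordered pair; symmetry is enforced at load time.
drug_drug_contra:
  detemir: [testosterone, beta-blockers, decongestants, hydrochlorothiazide]
  aspart: [gatifloxacin, macimorelin]

drug_disease_contra:
  aspart: [hypokalemia]

drug_food_contra:
  statins: [grapefruit]
  metformin: [alcohol]

disease_food_contra:
  celiac_disease: [gluten]
  nephropathy: [high_sodium_foods]

disease_exercise_contra:
  foot_ulcers: [jogging]
  cataracts: [cycling]
  severe_nonproliferative_retinopathy: [jumping, jarring, breath_holding]

hyperglycemic_drugs:
  [corticosteroid, octreotide, beta-blockers, epinephrine, thiazide_diuretics,
   statins, niacin, pentamidine, protease_inhibitors, antipsychotics]

hypoglycemic_drugs: [quinine]

exercise_catalog:
  walking:        {met: 3.5, display: walking, intensity: light}
  jogging:        {met: 7.0, display: jogging, intensity: moderate}
  cycling:        {met: 7.5, display: cycling, intensity: vigorous}
  swimming:       {met: 6.0, display: swimming laps, intensity: moderate}
  jumping:        {met: 8.0, display: jumping rope, intensity: vigorous}
  yoga:           {met: 2.5, display: yoga, intensity: light}

exercise_defaults: [walking, swimming, yoga]

# Conditions that make exercise inadvisable (eligibility gate).
exercise_forbidden_conditions:
  [hypertension, preeclampsia, dyslipidemia, preproliferative_retinopathy,
   nephropathy, cigarette_smoking]

pregnancy_exercise_contraindications:
  [preeclampsia, hypertension, morbid_obesity, placenta_previa,
   fetal_anemia, chronic_bronchitis]

exercise_component_defaults:
  frequency_per_week: {child: 5, adolescent: 5, adult: 4, oldAdult: 3}
  duration_min: {child: 30, adolescent: 30, adult: 30, oldAdult: 20}

# Glycemic goal templates per (age category, pregnancy) stratum. Only the
# pregnant-adult row is fixed by the encoded guideline rule; the others are
# synthetic defaults in the style of consensus guidelines and are expected
# to be overridden per site. Glucose values in mg/dL, HbA1c in percent.
goal_defaults:
  adult_pregnant:    {hba1c_max: 6.5, premeal_low: 90, premeal_high: 100,
                      bedtime_low: 100, bedtime_high: 140}
  adolescent_pregnant: {hba1c_max: 6.5, premeal_low: 90, premeal_high: 100,
                      bedtime_low: 100, bedtime_high: 140}
  child:             {hba1c_max: 7.5, premeal_low: 90, premeal_high: 130,
                      bedtime_low: 90, bedtime_high: 150}
  adolescent:        {hba1c_max: 7.5, premeal_low: 90, premeal_high: 130,
                      bedtime_low: 90, bedtime_high: 150}
  adult:             {hba1c_max: 7.0, premeal_low: 80, premeal_high: 130,
                      bedtime_low: 90, bedtime_high: 150}
  oldAdult:          {hba1c_max: 8.0, premeal_low: 90, premeal_high: 150,
                      bedtime_low: 100, bedtime_high: 180}

# Adjustments layered on the stratum template.
goal_overrides:
  hypoglycemia_history_hba1c_relax: 0.5
  hypoglycemia_history_premeal_low_raise: 10

learning_styles:
  child:           {low: [games, visual], medium: [games, visual], high: [games, visual]}
  adolescent:      {low: [games, visual], medium: [visual], high: [visual, reading]}
  adult:           {low: [auditory, visual], medium: [visual], high: [visual, reading]}
  oldAdult:        {low: [auditory, visual], medium: [auditory, visual], high: [reading, visual]}

course_catalog:
  insulin:
    reading: [INS-R01-types, INS-R02-injection, INS-R03-storage]
    visual: [INS-V01-regimens]
    auditory: [INS-A01-basics]
    games: [INS-G01-dose-quiz]
  medications:
    reading: [MED-R01-administration]
    visual: [MED-V01-side-effects]
  diet:
    reading: [DIET-R01-carb-counting]
    visual: [DIET-V01-food-groups]
    auditory: [DIET-A01-meal-planning]
    games: [DIET-G01-carb-game]
  monitoring:
    reading: [MON-R01-pattern-management, MON-R02-isf-icr]
    visual: [MON-V01-glucose-diary]
    auditory: [MON-A01-sensor-use]
    games: [MON-G01-target-game]
  emergency:
    reading: [EMR-R01-hypo-symptoms]
    visual: [EMR-V01-hyper-response]
    auditory: [EMR-A01-first-aid]
  exercise:
    reading: [EXR-R01-sport-selection]
    visual: [EXR-V01-calorie-burn]
  complications:
    reading: [CMP-R01-overview]
    visual: [CMP-V01-foot-care]

food_groups:
  [vegetables, whole_grains, fruits, lean_protein, low_fat_dairy, legumes]
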