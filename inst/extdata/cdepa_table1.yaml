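# Default CDEPA rule map: symptom checklist with certainty levels and the
# combination-rule parameters.  This file is data, not code: edit it to
# adjust level assignments without touching the engine.
#
# NOTE FOR REVIEW: the certainty column of the published flattened table is
# ambiguous for the entries marked "column-unresolved" below (symptomatic
# dysautonomia, excessive daytime somnolence, moderate-severe apathy,
# psychotic symptoms, mild cognitive impairment).  The defaults here follow
# the structure of the original Delphi instrument; verify against it before
# clinical use.
promotion_b_min_areas: 2
diagnosis_threshold: definitive
symptoms:
  - id: evolution_10y
    label: "Evolution time (around 10 years)"
    area: general_characteristics
    level: probable
  - id: disability_help_adl
    label: "Requiring help to perform daily living activities"
    area: disability
    level: definitive
  - id: disability_limit_no_help
    label: "Limitation to perform basic activities, although not requiring help"
    area: disability
    level: probable
  - id: fluctuations_off25_limit
    label: "Motor fluctuations with an off time >25%, with limitation to perform the basic activities without requiring help"
    area: treatment_motor
    level: definitive
  - id: dyskinesia_on25
    label: "Functional disability due to dyskinesias with an on time >25%"
    area: treatment_motor
    level: probable
  - id: severe_dysphagia
    label: "Severe dysphagia"
    area: disease_motor
    level: definitive
  - id: recurrent_falls
    label: "Recurrent falls"
    area: disease_motor
    level: definitive
  - id: moderate_dysphagia
    label: "Moderate dysphagia"
    area: disease_motor
    level: probable
  - id: freezing_gait
    label: "Freezing of gait"
    area: disease_motor
    level: probable
  - id: dysarthria_moderate_severe
    label: "Moderate-severe dysarthria"
    area: disease_motor
    level: possible
  - id: postural_equilibrium
    label: "Postural and equilibrium disorders"
    area: disease_motor
    level: possible
  - id: symptomatic_dysautonomia   # column-unresolved
    label: "Symptomatic dysautonomia, including orthostatic symptomatic hypotension"
    area: disease_non_motor
    level: possible
  - id: daytime_somnolence         # column-unresolved
    label: "Excessive daytime somnolence"
    area: disease_non_motor
    level: possible
  - id: dementia
    label: "Dementia"
    area: neuropsychiatric_cognitive
    level: definitive
  - id: hallucinations_no_insight
    label: "Hallucinations without preserved insight"
    area: neuropsychiatric_cognitive
    level: probable
  - id: apathy_moderate_severe     # column-unresolved
    label: "Moderate-severe apathy"
    area: neuropsychiatric_cognitive
    level: probable
  - id: chronic_hallucinations_insight
    label: "Chronic presence of hallucinations with preserved insight"
    area: neuropsychiatric_cognitive
    level: possible
  - id: psychotic_symptoms         # column-unresolved
    label: "Psychotic symptoms"
    area: neuropsychiatric_cognitive
    level: possible
  - id: mild_cognitive_impairment  # column-unresolved
    label: "Mild cognitive impairment"
    area: neuropsychiatric_cognitive
    level: possible
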