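# Default LaD configuration.
#
# The factorization is one consistent reconstruction of the algorithm's
# scenario space: the product of the factor cardinalities must equal
# `expect_total_scenarios` (3 x 4 x 4 x 4 x 2 x 3 = 1152) and is verified at
# load time.  Normal ranges and monitoring intervals follow WHO intrapartum
# conventions and are fully overridable; none of the validation statistics
# depend on the label wording.

name: lad-default
expect_total_scenarios: 1152
n_actions: 22
max_actions_per_case: 16
active_phase_start_cm: 5

parameters:
  - name: fetal_heart_rate
    kind: continuous
    unit: bpm
    physical_range: [20, 260]
    states: [abnormal_low, normal, abnormal_high]
    normal_states: [normal]
    breaks: [110, 161]          # normal band 110-160 bpm inclusive
    interval_minutes: 30
    stage: both
  - name: amniotic_fluid
    kind: categorical
    states: [intact, clear, opaque_or_foul]
    normal_states: [intact, clear]
    aliases:
      intact: intact
      membranes_intact: intact
      clear: clear
      fluid_clear: clear
      opaque: opaque_or_foul
      foul: opaque_or_foul
      foul_smelling: opaque_or_foul
      meconium: opaque_or_foul
    interval_minutes: 240       # assessed at each 4-hourly vaginal examination
    stage: both
  - name: cervical_dilatation
    kind: continuous
    unit: cm_per_hour           # active-phase progress rate between examinations
    physical_range: [0, 10]
    states: [inadequate_progress, adequate_progress]
    normal_states: [adequate_progress]
    breaks: [1]                 # partograph alert-line convention, 1 cm/h
    interval_minutes: 240
    stage: first
  - name: uterine_contractions
    kind: continuous
    unit: per_10min
    physical_range: [0, 10]
    states: [inadequate, adequate, excessive]
    normal_states: [adequate]
    breaks: [3, 6]              # 3-5 contractions per 10 min adequate
    interval_minutes: 30
    stage: both
  - name: blood_pressure
    kind: composite
    components:
      systolic:  {physical_range: [40, 300], normal_below: 140}
      diastolic: {physical_range: [20, 200], normal_below: 90}
    states: [normal, hypertensive]
    normal_states: [normal]
    interval_minutes: 240
    stage: both
  - name: fetal_station
    kind: continuous
    unit: station
    physical_range: [-5, 5]
    states: [not_descended, descending]
    normal_states: [descending]
    breaks: [0]
    interval_minutes: 30
    stage: second

factorization:
  - name: amniotic_status
    states: [membranes_intact, fluid_clear, fluid_opaque_or_foul]
    normal_states: [membranes_intact, fluid_clear]
  - name: fetal_heart_rate
    states: [normal, abnormal_recovered, abnormal_persistent, severe_abnormal]
    normal_states: [normal]
  - name: cervical_progress
    states: [adequate, slow_responding, slow_persistent, arrested]
    normal_states: [adequate]
  - name: uterine_contractions
    states: [adequate, inadequate_responding, inadequate_persistent, hyperstimulation]
    normal_states: [adequate]
  - name: blood_pressure
    states: [normal, hypertensive]
    normal_states: [normal]
  - name: fetal_descent
    states: [progressing, delayed, obstructed]
    normal_states: [progressing]

actions:
  - {id: 1,  label: continue routine partograph monitoring,      category: observe}
  - {id: 2,  label: increase fetal heart rate monitoring,        category: observe}
  - {id: 3,  label: repeat vaginal examination in 2 hours,       category: observe}
  - {id: 4,  label: reposition mother to left lateral,           category: intervene}
  - {id: 5,  label: start intravenous fluids,                    category: intervene}
  - {id: 6,  label: administer oxygen by mask,                   category: intervene}
  - {id: 7,  label: stop oxytocin infusion,                      category: intervene}
  - {id: 8,  label: start or augment oxytocin,                   category: intervene}
  - {id: 9,  label: perform amniotomy,                           category: intervene}
  - {id: 10, label: administer antihypertensive,                 category: intervene}
  - {id: 11, label: administer magnesium sulfate,                category: intervene}
  - {id: 12, label: start broad-spectrum antibiotics,            category: intervene}
  - {id: 13, label: administer tocolytic,                        category: intervene}
  - {id: 14, label: catheterize bladder,                         category: intervene}
  - {id: 15, label: encourage mobilization and oral hydration,   category: intervene}
  - {id: 16, label: fetal scalp stimulation test,                category: observe}
  - {id: 17, label: notify senior obstetrician,                  category: escalate}
  - {id: 18, label: transfer to comprehensive obstetric facility, category: escalate}
  - {id: 19, label: prepare theatre for cesarean section,        category: deliver}
  - {id: 20, label: expedite operative vaginal delivery,         category: deliver}
  - {id: 21, label: start continuous electronic fetal monitoring, category: observe}
  - {id: 22, label: reassess in 30 minutes,                      category: observe}

# Management rules: one per non-normal factor state.  `resolved` encodes the
# success or failure of managing that subabnormality (a property of the
# scenario coordinate, not a random draw); `critical` marks unresolved states
# that force the escalation track of the final decision.
rules:
  - {factor: amniotic_status, state: fluid_opaque_or_foul,
     actions: [12, 2, 17], resolved: false, critical: true}
  - {factor: fetal_heart_rate, state: abnormal_recovered,
     actions: [4, 5, 6, 22], resolved: true, critical: false}
  - {factor: fetal_heart_rate, state: abnormal_persistent,
     actions: [4, 6, 21, 17], resolved: false, critical: true}
  - {factor: fetal_heart_rate, state: severe_abnormal,
     actions: [6, 7, 17, 19], resolved: false, critical: true}
  - {factor: cervical_progress, state: slow_responding,
     actions: [15, 9, 3], resolved: true, critical: false}
  - {factor: cervical_progress, state: slow_persistent,
     actions: [8, 3, 14], resolved: false, critical: true}
  - {factor: cervical_progress, state: arrested,
     actions: [17, 19], resolved: false, critical: true}
  - {factor: uterine_contractions, state: inadequate_responding,
     actions: [15, 9, 22], resolved: true, critical: false}
  - {factor: uterine_contractions, state: inadequate_persistent,
     actions: [8, 22], resolved: false, critical: true}
  - {factor: uterine_contractions, state: hyperstimulation,
     actions: [7, 13, 4], resolved: false, critical: true}
  - {factor: blood_pressure, state: hypertensive,
     actions: [10, 11, 17], resolved: false, critical: true}
  - {factor: fetal_descent, state: delayed,
     actions: [14, 15, 22], resolved: true, critical: false}
  - {factor: fetal_descent, state: obstructed,
     actions: [7, 17, 19], resolved: false, critical: true}

final_decision:
  routine_actions: [1]
  escalation_actions: [17, 19]
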