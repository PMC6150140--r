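variables:
- name: mothers_age
  domain: maternal history
  kind: numeric
  introduced_in: revised2014
  range:
    min: 12.0
    max: 55.0
- name: parity
  domain: maternal history
  kind: numeric
  introduced_in: revised2014
  range:
    min: 0.0
    max: 15.0
- name: gravidity
  domain: maternal history
  kind: numeric
  introduced_in: revised2014
  range:
    min: 1.0
    max: 15.0
- name: mothers_blood_group
  domain: maternal history
  kind: categorical
  introduced_in: revised2014
  categories:
  - A+
  - A-
  - B+
  - B-
  - AB+
  - AB-
  - O+
  - O-
- name: hiv_status
  domain: maternal history
  kind: categorical
  introduced_in: revised2014
  categories:
  - positive
  - negative
  - unknown
- name: vdrl_status
  domain: maternal history
  kind: categorical
  introduced_in: revised2014
  categories:
  - reactive
  - non_reactive
  - unknown
- name: date_of_birth
  domain: demographics and diagnosis
  kind: date
  introduced_in: baseline
- name: admission_date
  domain: demographics and diagnosis
  kind: date
  introduced_in: baseline
- name: gender
  domain: demographics and diagnosis
  kind: categorical
  introduced_in: baseline
  categories:
  - male
  - female
- name: birth_weight
  domain: demographics and diagnosis
  kind: numeric
  introduced_in: baseline
  range:
    min: 0.4
    max: 6.0
- name: age_in_days
  domain: demographics and diagnosis
  kind: numeric
  introduced_in: baseline
  range:
    min: 0.0
    max: 28.0
- name: gestational_age
  domain: demographics and diagnosis
  kind: numeric
  introduced_in: baseline
  range:
    min: 22.0
    max: 44.0
- name: mode_of_delivery
  domain: demographics and diagnosis
  kind: categorical
  introduced_in: baseline
  categories:
  - svd
  - caesarean_section
  - breech
  - assisted
- name: apgar_5min
  domain: demographics and diagnosis
  kind: numeric
  introduced_in: baseline
  range:
    min: 0.0
    max: 10.0
- name: admission_diagnosis
  domain: demographics and diagnosis
  kind: text
  introduced_in: baseline
- name: discharge_date
  domain: demographics and diagnosis
  kind: date
  introduced_in: baseline
- name: outcome
  domain: demographics and diagnosis
  kind: categorical
  introduced_in: baseline
  categories:
  - alive
  - dead
- name: discharge_diagnosis
  domain: demographics and diagnosis
  kind: text
  introduced_in: baseline
- name: fever
  domain: presenting complaints
  kind: categorical
  introduced_in: baseline
  categories:
  - 'yes'
  - 'no'
- name: convulsions
  domain: presenting complaints
  kind: categorical
  introduced_in: baseline
  categories:
  - 'yes'
  - 'no'
- name: difficulty_breathing
  domain: presenting complaints
  kind: categorical
  introduced_in: baseline
  categories:
  - 'yes'
  - 'no'
- name: vomiting
  domain: presenting complaints
  kind: categorical
  introduced_in: baseline
  categories:
  - 'yes'
  - 'no'
- name: difficulty_feeding
  domain: presenting complaints
  kind: categorical
  introduced_in: baseline
  categories:
  - 'yes'
  - 'no'
- name: apnoea
  domain: presenting complaints
  kind: categorical
  introduced_in: baseline
  categories:
  - 'yes'
  - 'no'
- name: grunting
  domain: cardinal signs on examination
  kind: categorical
  introduced_in: baseline
  categories:
  - 'yes'
  - 'no'
- name: central_cyanosis
  domain: cardinal signs on examination
  kind: categorical
  introduced_in: baseline
  categories:
  - 'yes'
  - 'no'
- name: bulging_fontanelle
  domain: cardinal signs on examination
  kind: categorical
  introduced_in: baseline
  categories:
  - 'yes'
  - 'no'
- name: floppy
  domain: cardinal signs on examination
  kind: categorical
  introduced_in: baseline
  categories:
  - 'yes'
  - 'no'
- name: stridor
  domain: other physical examination
  kind: categorical
  introduced_in: revised2014
  categories:
  - 'yes'
  - 'no'
- name: bilateral_air_entry
  domain: other physical examination
  kind: categorical
  introduced_in: revised2014
  categories:
  - 'yes'
  - 'no'
- name: crackles
  domain: other physical examination
  kind: categorical
  introduced_in: baseline
  categories:
  - 'yes'
  - 'no'
- name: chest_indrawing
  domain: other physical examination
  kind: categorical
  introduced_in: baseline
  categories:
  - 'yes'
  - 'no'
- name: skin_pinch
  domain: other physical examination
  kind: categorical
  introduced_in: baseline
  categories:
  - 'yes'
  - 'no'
- name: femoral_pulses
  domain: other physical examination
  kind: categorical
  introduced_in: revised2014
  categories:
  - 'yes'
  - 'no'
- name: capillary_refill_time
  domain: other physical examination
  kind: numeric
  introduced_in: baseline
  range:
    min: 0.0
    max: 10.0
- name: heart_murmur
  domain: other physical examination
  kind: categorical
  introduced_in: revised2014
  categories:
  - 'yes'
  - 'no'
- name: pallor
  domain: other physical examination
  kind: categorical
  introduced_in: baseline
  categories:
  - 'yes'
  - 'no'
- name: skin_temperature_gradient
  domain: other physical examination
  kind: categorical
  introduced_in: revised2014
  categories:
  - 'yes'
  - 'no'
- name: eye_infection
  domain: other physical examination
  kind: categorical
  introduced_in: baseline
  categories:
  - 'yes'
  - 'no'
- name: umbilical_infection
  domain: other physical examination
  kind: categorical
  introduced_in: baseline
  categories:
  - 'yes'
  - 'no'
- name: skin_rashes
  domain: other physical examination
  kind: categorical
  introduced_in: baseline
  categories:
  - 'yes'
  - 'no'
- name: stiff_neck
  domain: other physical examination
  kind: categorical
  introduced_in: baseline
  categories:
  - 'yes'
  - 'no'
- name: irritability
  domain: other physical examination
  kind: categorical
  introduced_in: baseline
  categories:
  - 'yes'
  - 'no'
- name: jaundice
  domain: other physical examination
  kind: categorical
  introduced_in: baseline
  categories:
  - 'yes'
  - 'no'
- name: gestational_size
  domain: other physical examination
  kind: categorical
  introduced_in: revised2014
  categories:
  - sga
  - aga
  - lga
- name: severe_wasting
  domain: other physical examination
  kind: categorical
  introduced_in: revised2014
  categories:
  - 'yes'
  - 'no'
- name: temperature
  domain: vital signs
  kind: numeric
  introduced_in: baseline
  range:
    min: 30.0
    max: 42.0
- name: respiratory_rate
  domain: vital signs
  kind: numeric
  introduced_in: baseline
  range:
    min: 10.0
    max: 120.0
- name: heart_rate
  domain: vital signs
  kind: numeric
  introduced_in: baseline
  range:
    min: 40.0
    max: 250.0
- name: oxygen_saturation
  domain: vital signs
  kind: numeric
  introduced_in: revised2014
  range:
    min: 0.0
    max: 100.0
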