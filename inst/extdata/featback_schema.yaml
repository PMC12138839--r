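# Default 12-attribute schema for a Featback-style eating-disorder cohort.
# higher_is_worse: false marks attributes whose raw scale points the "good"
# way; the pipeline reverse-codes them before analysis. Whether self-rated
# health is reverse-coded is a schema choice -- edit here, not in code.
- name: bmi
  label: BMI
  higher_is_worse: false
- name: social_support
  label: Social support
  higher_is_worse: false
- name: self_efficacy
  label: Self-efficacy
  higher_is_worse: false
- name: edeq_global
  label: ED psychopathology
  higher_is_worse: true
- name: binge_eating
  label: Binge eating
  higher_is_worse: true
- name: vomiting
  label: Vomiting
  higher_is_worse: true
- name: laxative_use
  label: Laxative use
  higher_is_worse: true
- name: anxiety
  label: Anxiety
  higher_is_worse: true
- name: depression
  label: Depression
  higher_is_worse: true
- name: wellbeing
  label: Well-being
  higher_is_worse: false
- name: hrqol
  label: HR quality of life
  higher_is_worse: false
- name: self_rated_health
  label: Self-rated health
  higher_is_worse: false
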