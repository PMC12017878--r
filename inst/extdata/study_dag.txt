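age delay
age survival
bmi delay
bmi survival
comorbidity delay
comorbidity survival
complications survival
delay complications
delay stage_migration
delay survival
delay treatment_intensity
family_history delay
family_history survival
stage_migration survival
subtype delay
subtype survival
treatment_intensity survival
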