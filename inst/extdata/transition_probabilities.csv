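from,to,stratum_key,stratum_value,probability
Symptomatic-Undiagnosed,Diagnosed-Untreated,Overall,Overall,0.302
Symptomatic-Undiagnosed,Diagnosed-Untreated,Symptom Type,Breast lump,0.355
Symptomatic-Undiagnosed,Diagnosed-Untreated,Symptom Type,Pain,0.217
Symptomatic-Undiagnosed,Diagnosed-Untreated,Symptom Type,Nipple discharge,0.196
Symptomatic-Undiagnosed,Diagnosed-Untreated,Time Interval,<2w,0.930
Symptomatic-Undiagnosed,Diagnosed-Untreated,Time Interval,2w-1m,0.868
Symptomatic-Undiagnosed,Diagnosed-Untreated,Time Interval,1-2m,0.937
Symptomatic-Undiagnosed,Diagnosed-Untreated,Time Interval,2-6m,0.623
Symptomatic-Undiagnosed,Diagnosed-Untreated,Time Interval,6-12m,0.906
Symptomatic-Undiagnosed,Diagnosed-Untreated,Time Interval,>=1y,0.736
Diagnosed-Untreated,Treatment-Initiated,Overall,Overall,0.424
Diagnosed-Untreated,Treatment-Initiated,Stage,IIA,0.476
Diagnosed-Untreated,Treatment-Initiated,Stage,IIB,0.431
Diagnosed-Untreated,Treatment-Initiated,Stage,III/IV,0.383
Treatment-Initiated,Progressive-Disease,Overall,Overall,0.103
Treatment-Initiated,Progressive-Disease,Molecular Subtype,HR+,0.078
Treatment-Initiated,Progressive-Disease,Molecular Subtype,TripleNegative,0.138
Treatment-Initiated,Progressive-Disease,Molecular Subtype,HER2+,0.115
Treatment-Initiated,Progressive-Disease,Treatment Type,Surgery only,0.062
Treatment-Initiated,Progressive-Disease,Treatment Type,Surgery + Chemotherapy,0.126
Treatment-Initiated,Progressive-Disease,Treatment Type,Multimodality,0.143
Treatment-Initiated,Death,Overall,Overall,0.021
Progressive-Disease,Death,Overall,Overall,0.085
Progressive-Disease,Death,Stage at Diagnosis,IIA,0.046
Progressive-Disease,Death,Stage at Diagnosis,IIB,0.073
Progressive-Disease,Death,Stage at Diagnosis,III,0.119
Progressive-Disease,Death,Stage at Diagnosis,IV,0.215
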