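group,month,probability
StageI-II,1,0.038
StageI-II,3,0.117
StageI-II,6,0.245
StageI-II,12,0.429
StageII-III,1,0.027
StageII-III,3,0.082
StageII-III,6,0.178
StageII-III,12,0.336
StageIII-IV,1,0.019
StageIII-IV,3,0.058
StageIII-IV,6,0.121
StageIII-IV,12,0.243
HR+,1,0.021
HR+,3,0.065
HR+,6,0.137
HR+,12,0.258
TripleNegative,1,0.053
TripleNegative,3,0.159
TripleNegative,6,0.318
TripleNegative,12,0.536
HER2+,1,0.038
HER2+,3,0.114
HER2+,6,0.228
HER2+,12,0.427
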