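patient_id,diagnosis
P01,CSA
P02,CSA
P03,CSA
P04,CSA
P05,CSA
P06,CSA
P07,CSA
P08,OSA
P09,OSA
P10,OSA
P11,OSA
P12,OSA
P13,OSA
P14,none
P15,none
P16,none
P17,none
P18,none
P19,none
P20,none
P21,none
P22,none
P23,CSA
P24,none
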