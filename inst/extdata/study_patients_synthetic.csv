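patient_id,diagnosis,odi_mobile,odi_poly
P01,CSA,24.3,31.2
P02,CSA,18.8,27.5
P03,CSA,16.2,22.0
P04,CSA,12.4,25.1
P05,CSA,9.7,19.4
P06,CSA,6.1,16.8
P07,CSA,3.0,13.2
P08,OSA,28.6,34.0
P09,OSA,20.3,26.7
P10,OSA,15.0,21.9
P11,OSA,13.1,18.3
P12,OSA,10.8,16.2
P13,OSA,7.9,15.4
P14,none,22.7,9.8
P15,none,19.5,7.4
P16,none,17.3,5.1
P17,none,15.6,3.9
P18,none,11.2,2.2
P19,none,8.4,6.0
P20,none,5.3,1.4
P21,none,2.9,4.7
P22,none,1.1,0.8
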