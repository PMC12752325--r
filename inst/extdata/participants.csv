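participant_id,age,sex,time_since_stroke_months,hemisphere,fma_ue
P1,76,F,57,L,60
P2,79,F,157,R,60
P3,73,M,2,L,62
P4,79,M,128,R,60
P5,67,F,261,L,40
P6,77,M,50,R,66
P7,77,F,157,R,63
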