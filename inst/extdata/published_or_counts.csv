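predictor,a,b,c,d
t_stage_1_2,20,33,2,27
anatomic_stage_iia_iiia,20,46,2,14
grade_3,11,28,8,30
ki67_high,9,35,8,25
er_negative,18,37,4,23
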