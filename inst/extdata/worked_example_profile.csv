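n_abortions,age_first_birth,benign_breast_disease,height_m,weight_kg,family_history,satisfaction_1,satisfaction_2,satisfaction_3,satisfaction_4,satisfaction_5,satisfaction_6
1,27,0,1.6,69.12,1,1,1,1,1,1,2
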