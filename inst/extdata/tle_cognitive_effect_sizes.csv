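measure,mean_patient,sd_patient,mean_control,sd_control,n_patient,n_control,published_p,published_d
g,-0.307,0.876,0.427,0.846,110,79,0.000,0.850
lda,-0.407,0.841,0.567,0.929,110,79,0.000,1.109
block_design,-0.185,0.938,0.257,1.033,110,79,0.035,0.452
vocabulary,-0.269,0.913,0.375,1.000,110,79,0.000,0.677
line_orientation,-0.210,1.110,0.292,0.735,110,79,0.009,0.516
motor_speed,-0.280,0.917,0.390,0.985,110,79,0.000,0.709
letter_fluency,-0.079,1.042,0.110,0.934,110,79,1.000,0.190
semantic_fluency,-0.107,1.017,0.148,0.963,110,79,1.000,0.256
verbal_learning,-0.310,0.955,0.432,0.901,110,79,0.000,0.796
delayed_recall,-0.277,0.999,0.386,0.870,110,79,0.000,0.700
naming,-0.165,1.012,0.230,0.942,110,79,0.097,0.401
attention_inhibition,-0.189,0.872,0.263,1.108,110,79,0.028,0.463
working_memory,-0.125,1.045,0.174,0.912,110,79,0.555,0.301
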