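metric,mode,v_inj,q_inj,value
entrainment,continuous,0.05,0.3,0.1646
entrainment,continuous,0.05,0.6,0.0015
entrainment,continuous,0.05,0.9,-0.1084
entrainment,continuous,0.05,1.2,-0.2263
entrainment,continuous,0.1,0.3,0.2125
entrainment,continuous,0.1,0.6,0.0389
entrainment,continuous,0.1,0.9,-0.086
entrainment,continuous,0.1,1.2,-0.2265
entrainment,continuous,0.15,0.3,0.1985
entrainment,continuous,0.15,0.6,0.0144
entrainment,continuous,0.15,0.9,-0.0866
entrainment,continuous,0.15,1.2,-0.2454
entrainment,pulsed,0.015,0.3,0.04412
entrainment,pulsed,0.015,0.6,-0.14936
entrainment,pulsed,0.015,0.9,-0.4581
entrainment,pulsed,0.015,1.2,-0.7167
entrainment,pulsed,0.02,0.3,0.04964
entrainment,pulsed,0.02,0.6,-0.1353
entrainment,pulsed,0.02,0.9,-0.33948
entrainment,pulsed,0.02,1.2,-0.60956
relaxation,continuous,0.05,0.3,0.497
relaxation,continuous,0.05,0.6,0.891
relaxation,continuous,0.05,0.9,0.398
relaxation,continuous,0.05,1.2,0.198
relaxation,continuous,0.1,0.3,0.103
relaxation,continuous,0.1,0.6,0.100
relaxation,continuous,0.1,0.9,0.509
relaxation,continuous,0.1,1.2,0.504
relaxation,continuous,0.15,0.3,0.495
relaxation,continuous,0.15,0.6,0.607
relaxation,continuous,0.15,0.9,0.399
relaxation,continuous,0.15,1.2,0.107
relaxation,pulsed,0.015,0.3,0.715
relaxation,pulsed,0.015,0.6,0.341
relaxation,pulsed,0.015,0.9,0.118
relaxation,pulsed,0.015,1.2,0.151
relaxation,pulsed,0.02,0.3,0.196
relaxation,pulsed,0.02,0.6,0.315
relaxation,pulsed,0.02,0.9,0.809
relaxation,pulsed,0.02,1.2,0.021
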