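region,class,count
globus_pallidus_externus,STN-afferent,42
globus_pallidus_externus,STN-efferent,18
globus_pallidus_internus,STN-afferent,8
globus_pallidus_internus,STN-efferent,30
substantia_nigra,STN-afferent,14
substantia_nigra,STN-efferent,36
pedunculopontine_nucleus,STN-afferent,20
pedunculopontine_nucleus,STN-efferent,16
motor_cortex,STN-afferent,25
striatum,STN-efferent,10
thalamus_parafascicular,STN-afferent,12
thalamus_parafascicular,STN-efferent,6
lateral_hypothalamus,paraSTN-afferent,7
lateral_hypothalamus,paraSTN-efferent,9
amygdala_central,paraSTN-afferent,5
amygdala_central,paraSTN-efferent,4
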