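polymer,density_g_per_cm3
PE,0.95
HDPE,0.96
LDPE,0.92
PP,0.905
PS,1.05
PVC,1.38
PET,1.38
PA,1.14
PLA,1.25
PC,1.2
PMMA,1.18
PU,1.2
EVA,0.93
PBAT,1.26
ABS,1.06
PTFE,2.2
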