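bone,volume_cv,sa_cv
pelvis,13.54,8.74
femur,17.23,12.17
patella,17.38,11.85
tibia_fibula,17.33,13.40
foot,14.24,10.92
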