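specimen,bone,scan,mean_mm
1,femur,CT2,0.38
1,femur,CT3,0.38
1,femur,CT4,0.61
1,pelvis,CT2,0.52
1,pelvis,CT3,0.60
1,tibia,CT2,0.63
1,tibia,CT3,0.34
1,tibia,CT4,0.68
1,patella,CT4,0.60
2,femur,CT2,0.40
2,femur,CT3,0.45
2,femur,CT4,0.71
2,pelvis,CT2,0.40
2,pelvis,CT3,0.39
2,tibia,CT2,0.47
2,tibia,CT3,0.45
2,tibia,CT4,0.49
2,patella,CT4,0.92
3,femur,CT2,0.37
3,femur,CT3,0.34
3,femur,CT4,0.66
3,pelvis,CT2,0.31
3,pelvis,CT3,0.32
3,tibia,CT2,0.69
3,tibia,CT3,0.71
3,tibia,CT4,0.74
3,patella,CT4,0.74
4,femur,CT2,0.34
4,femur,CT3,0.39
4,femur,CT4,0.64
4,pelvis,CT2,0.32
4,pelvis,CT3,0.34
4,tibia,CT2,0.35
4,tibia,CT3,0.30
4,tibia,CT4,0.65
4,patella,CT4,0.54
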