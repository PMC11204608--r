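attachment,role,area_mean_mm2,area_std_mm2,cv
gastrocnemius_caput_mediale,O,630.12,182.71,29.00
gastrocnemius_caput_laterale,O,788.24,293.77,37.27
achilles_tendon,I,1000.21,129.47,12.94
rectus_femoris_caput_rectum,O,282.42,73.21,25.92
rectus_femoris_caput_reflexum,O,366.77,216.17,58.94
biceps_femoris_caput_longum,O,260.42,162.77,62.50
biceps_femoris_caput_breve,O,582.20,259.99,44.66
biceps_femoris_tibial,I,103.86,82.87,79.79
biceps_femoris_fibular,I,401.88,94.16,23.43
semimembranosus,O,471.78,48.69,10.32
semimembranosus,I,1048.10,304.77,29.08
semitendinosus,O,604.32,155.25,25.69
semitendinosus,I,226.50,120.11,53.03
sartorius,O,115.94,19.92,17.18
sartorius,I,313.18,250.69,80.05
gracilis,O,132.23,46.13,34.88
gracilis,I,67.18,22.78,33.90
vastus_lateralis,O,2493.56,82.11,3.29
vastus_medialis,O,3410.55,541.07,15.86
vastus_intermedius,O,10968.48,849.01,7.74
quadriceps_tendon,I,1480.95,271.94,18.36
patellar_tendon,O,992.16,305.28,30.77
patellar_tendon,I,733.14,198.92,27.13
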