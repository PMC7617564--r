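region,condition,bd_mean,bd_sd,cbf_mean,cbf_sd,macro_bv_mean,macro_bv_sd,tmacro_mean,tmacro_sd
caudate,vc2,1.58,0.24,35,9,0.0010,0.0007,1.22,0.17
cerebellum,vc2,2.41,0.46,53,9,0.0010,0.0007,1.22,0.17
frontal_lobe,vc2,2.02,0.26,52,8,0.0010,0.0007,1.22,0.17
insula,vc2,1.88,0.49,43,4,0.0010,0.0007,1.22,0.17
occipital_lobe,vc2,2.39,0.48,71,11,0.0010,0.0007,1.22,0.17
parietal_lobe,vc2,2.38,0.42,66,7,0.0010,0.0007,1.22,0.17
putamen,vc2,1.92,0.76,37,11,0.0010,0.0007,1.22,0.17
temporal_lobe,vc2,2.05,0.44,53,8,0.0010,0.0007,1.22,0.17
thalamus,vc2,2.65,0.59,63,17,0.0010,0.0007,1.22,0.17
grey_matter,vc2,2.20,0.35,57,8,0.0010,0.0007,1.22,0.17
caudate,vc3,1.60,0.34,36,8,0.0010,0.0007,1.22,0.11
cerebellum,vc3,2.33,0.51,50,9,0.0010,0.0007,1.22,0.11
frontal_lobe,vc3,1.94,0.30,52,8,0.0010,0.0007,1.22,0.11
insula,vc3,1.89,0.59,42,6,0.0010,0.0007,1.22,0.11
occipital_lobe,vc3,2.30,0.56,71,11,0.0010,0.0007,1.22,0.11
parietal_lobe,vc3,2.31,0.52,65,9,0.0010,0.0007,1.22,0.11
putamen,vc3,2.03,0.74,36,11,0.0010,0.0007,1.22,0.11
temporal_lobe,vc3,2.07,0.53,52,7,0.0010,0.0007,1.22,0.11
thalamus,vc3,2.75,0.76,58,14,0.0010,0.0007,1.22,0.11
grey_matter,vc3,2.22,0.53,56,8,0.0010,0.0007,1.22,0.11
caudate,vc4,1.77,0.51,32,6,0.0010,0.0007,1.21,0.13
cerebellum,vc4,2.16,0.51,47,10,0.0010,0.0007,1.21,0.13
frontal_lobe,vc4,1.90,0.38,52,10,0.0010,0.0007,1.21,0.13
insula,vc4,1.95,0.45,39,7,0.0010,0.0007,1.21,0.13
occipital_lobe,vc4,2.14,0.26,68,12,0.0010,0.0007,1.21,0.13
parietal_lobe,vc4,2.15,0.40,63,11,0.0010,0.0007,1.21,0.13
putamen,vc4,1.94,0.80,29,11,0.0010,0.0007,1.21,0.13
temporal_lobe,vc4,2.01,0.51,50,8,0.0010,0.0007,1.21,0.13
thalamus,vc4,2.24,0.57,55,12,0.0010,0.0007,1.21,0.13
grey_matter,vc4,2.05,0.34,54,9,0.0010,0.0007,1.21,0.13
caudate,air,1.41,0.31,36,9,0.0010,0.0007,1.22,0.11
cerebellum,air,1.86,0.17,50,10,0.0010,0.0007,1.22,0.11
frontal_lobe,air,1.56,0.24,56,13,0.0010,0.0007,1.22,0.11
insula,air,1.42,0.25,48,7,0.0010,0.0007,1.22,0.11
occipital_lobe,air,1.76,0.20,67,15,0.0010,0.0007,1.22,0.11
parietal_lobe,air,1.68,0.20,67,14,0.0010,0.0007,1.22,0.11
putamen,air,1.44,0.28,40,12,0.0010,0.0007,1.22,0.11
temporal_lobe,air,1.56,0.23,54,11,0.0010,0.0007,1.22,0.11
thalamus,air,1.76,0.21,53,15,0.0010,0.0007,1.22,0.11
grey_matter,air,1.65,0.20,58,11,0.0010,0.0007,1.22,0.11
caudate,co2,1.15,0.30,47,14,0.0015,0.0007,1.22,0.11
cerebellum,co2,1.54,0.26,77,17,0.0015,0.0007,1.22,0.11
frontal_lobe,co2,1.31,0.25,82,22,0.0015,0.0007,1.22,0.11
insula,co2,1.25,0.26,63,18,0.0015,0.0007,1.22,0.11
occipital_lobe,co2,1.50,0.26,96,22,0.0015,0.0007,1.22,0.11
parietal_lobe,co2,1.46,0.25,95,20,0.0015,0.0007,1.22,0.11
putamen,co2,1.25,0.32,52,16,0.0015,0.0007,1.22,0.11
temporal_lobe,co2,1.36,0.24,72,14,0.0015,0.0007,1.22,0.11
thalamus,co2,1.49,0.27,88,23,0.0015,0.0007,1.22,0.11
grey_matter,co2,1.43,0.24,83,17,0.0015,0.0007,1.22,0.11
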