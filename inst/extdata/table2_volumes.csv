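# source: Table 2
# Paired structure volumes (cc) contoured on MRI and CT for ten patients.
patient_id,structure_or_metric,value_mri,value_ct
1,prostate,79.46,89.63
2,prostate,83.70,131.00
3,prostate,37.84,56.44
4,prostate,84.20,117.60
5,prostate,26.81,45.14
6,prostate,31.78,50.20
7,prostate,38.94,44.46
8,prostate,30.82,42.13
9,prostate,32.03,42.50
10,prostate,31.76,40.83
1,seminal_vesicles,16.43,19.96
2,seminal_vesicles,18.23,7.66
3,seminal_vesicles,16.22,14.19
4,seminal_vesicles,11.17,16.47
5,seminal_vesicles,6.85,9.02
6,seminal_vesicles,26.59,15.37
7,seminal_vesicles,22.92,17.27
8,seminal_vesicles,8.80,5.24
9,seminal_vesicles,9.44,12.64
10,seminal_vesicles,14.26,18.02
1,penile_bulb,2.63,3.02
2,penile_bulb,12.98,12.02
3,penile_bulb,3.95,4.45
4,penile_bulb,5.25,8.76
5,penile_bulb,1.95,4.98
6,penile_bulb,4.04,7.15
7,penile_bulb,3.64,4.93
8,penile_bulb,3.44,0.55
9,penile_bulb,2.81,4.74
10,penile_bulb,1.58,5.87
1,ctv,95.89,109.59
2,ctv,101.93,138.66
3,ctv,54.06,70.63
4,ctv,95.37,134.07
5,ctv,33.66,54.16
6,ctv,58.37,65.57
7,ctv,61.86,61.73
8,ctv,39.62,47.37
9,ctv,41.47,55.14
10,ctv,46.02,58.85
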