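# source: Table 4
# Per-patient mean and SD of daily CBCT couch shifts (cm), by reference
# modality. Patient 8 was not evaluable (metal artifacts). Per-patient
# fraction counts were not published; n_fractions is left blank.
# units: cm
patient_id,modality,ap_mean,ap_sd,si_mean,si_sd,lr_mean,lr_sd,n_fractions
1,CT,0.21,0.28,0.04,0.25,0.04,0.29,
2,CT,0.49,0.30,-0.02,0.54,0.07,0.36,
3,CT,0.04,0.61,0.06,0.53,0.06,0.51,
4,CT,0.10,0.23,0.18,0.24,-0.08,0.26,
5,CT,0.17,0.32,0.28,0.22,-0.06,0.36,
6,CT,0.26,0.42,0.02,0.24,0.16,0.19,
7,CT,-0.06,0.49,-0.18,0.88,0.11,0.64,
9,CT,-0.33,0.28,-0.10,0.16,0.30,0.25,
10,CT,0.36,0.30,0.05,0.15,-0.32,0.31,
1,MRI,-0.07,0.25,0.11,0.11,0.03,0.27,
2,MRI,0.44,0.28,0.03,0.54,0.04,0.33,
3,MRI,0.01,0.76,0.23,0.58,0.01,0.48,
4,MRI,0.02,0.15,0.02,0.15,0.00,0.00,
5,MRI,0.27,0.47,0.42,0.27,-0.15,0.38,
6,MRI,-0.02,0.33,0.10,0.20,0.10,0.18,
7,MRI,-0.63,0.49,-0.11,0.86,0.15,0.64,
9,MRI,-0.28,0.29,-0.02,0.11,0.29,0.27,
10,MRI,0.19,0.29,0.04,0.14,-0.31,0.33,
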