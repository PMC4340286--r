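# source: Table 3
# Paired plan dose metrics (Gy): CT heterogeneity-corrected calculation vs
# MRI bulk-density-assigned recalculation. Patient 8 excluded (hip
# prosthesis prevented bulk-density assignment). The published table's
# STDEV row prints negative values for D99/D95 and is not reproducible
# from these rows; the package reports the SD of the per-patient percent
# differences instead.
patient_id,structure_or_metric,value_mri,value_ct
1,plan_max,76.61,76.97
2,plan_max,82.43,79.58
3,plan_max,76.17,74.01
4,plan_max,74.81,75.17
5,plan_max,74.25,75.13
6,plan_max,78.02,77.05
7,plan_max,78.78,77.46
9,plan_max,81.59,79.62
10,plan_max,74.97,75.25
1,d99,72.45,73.70
2,d99,77.58,76.05
3,d99,70.24,69.78
4,d99,70.83,69.10
5,d99,70.54,72.01
6,d99,73.80,73.76
7,d99,73.67,73.42
9,d99,76.77,75.77
10,d99,70.63,72.03
1,d95,72.65,73.90
2,d95,77.82,76.30
3,d95,70.60,70.18
4,d95,71.15,70.89
5,d95,70.73,72.09
6,d95,73.94,73.92
7,d95,73.81,73.55
9,d95,76.98,75.95
10,d95,70.70,72.13
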