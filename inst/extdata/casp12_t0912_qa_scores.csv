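decoy_id,gdt_ts,fdubio,mufoldqa_c,davis_consensus,modfold6_cor,mufoldqa_s
T0912TS005_1,46.74,57.49,32.58,25.02,32.24,34.87
T0912TS220_1,45.47,57.19,34.96,26.41,34.37,36.12
T0912TS005_3,45.15,55.80,33.20,25.49,32.75,35.14
T0912TS005_4,44.83,56.63,31.95,24.55,32.00,34.32
T0912TS479_1,44.15,43.79,39.92,29.87,36.60,42.58
T0912TS005_5,43.85,47.40,33.32,25.56,33.01,35.65
T0912TS005_2,43.77,53.51,32.24,24.88,32.63,34.62
T0912TS479_4,42.47,42.06,38.18,28.47,34.80,41.02
T0912TS183_4,41.31,41.76,38.53,28.62,36.13,41.19
T0912TS287_1,40.79,41.63,37.45,28.41,35.20,38.94
T0912TS357_2,40.63,40.36,38.03,28.28,33.78,39.15
T0912TS236_1,40.63,41.52,37.47,28.43,35.05,38.99
T0912TS220_2,40.38,40.31,32.43,24.82,33.17,34.19
T0912TS357_3,40.10,39.83,37.91,28.20,33.79,39.15
T0912TS357_1,39.94,39.93,37.94,28.19,33.59,39.05
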