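patient,alternate,adjacent,three_to_zero,diploidy,others,nullisomy13,disomy13,aneuploidy13,total13,nullisomy14,disomy14,aneuploidy14,total14
11,62.39,35.02,1.34,0.67,0.57,22.01,3.54,25.55,26.79,8.42,3.73,12.15,13.40
12,62.03,34.19,3.08,0.50,0.20,17.30,6.16,23.46,24.16,12.82,4.08,16.90,17.59
13,75.73,22.59,1.31,0.37,0.00,10.78,4.12,14.90,15.28,4.97,5.34,10.31,10.68
14,78.04,18.69,2.27,0.49,0.49,6.92,3.26,10.19,11.18,5.84,7.22,13.06,14.05
15,79.28,18.30,2.06,0.00,0.36,7.17,6.01,13.18,13.54,5.11,4.13,9.24,9.60
16,71.29,26.43,1.81,0.19,0.29,6.37,6.84,13.21,13.69,10.65,6.18,16.83,17.30
17,85.53,13.38,0.69,0.40,0.00,3.27,3.07,6.34,6.74,6.24,2.18,8.42,8.82
18,65.89,32.95,0.87,0.10,0.19,6.57,6.96,13.53,13.82,14.11,7.05,21.16,21.45
19,80.24,16.22,2.80,0.37,0.37,4.75,6.06,10.81,11.56,7.27,3.73,11.00,11.74
20,83.32,16.48,0.10,0.00,0.10,3.50,5.19,8.69,8.79,4.70,3.30,7.99,8.09
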