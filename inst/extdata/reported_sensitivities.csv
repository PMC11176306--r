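analyte,unit,method_id,label,slope,slope_se,sensitivity_error_pct,lod
BTB,mg/L,1,R,-0.594,0.018,3.03,22.07
BTB,mg/L,2,G,-0.386,0.012,3.11,16.54
BTB,mg/L,3,B,-0.212,0.016,7.55,40.13
BTB,mg/L,4,(R+G+B)/3,-0.411,0.009,2.19,13.62
BTB,mg/L,5,log(R0/R),0.00164,0.00002,1.22,11.84
BTB,mg/L,6,log(G0/G),0.00087,0.00004,4.60,24.66
BTB,mg/L,7,log(B0/B),0.00043,0.00004,9.30,66.06
BTB,mg/L,8,R0-R,0.593,0.017,2.87,22.07
BTB,mg/L,9,G0-G,0.386,0.012,3.11,16.54
BTB,mg/L,10,B0-B,0.213,0.015,7.04,55.14
BTB,mg/L,11,dR+dG+dB,1.238,0.015,1.21,10.33
BTB,mg/L,12,(R+G+B)/R,0.00535,0.00007,1.31,6.79
BTB,mg/L,13,(R+G+B)/G,-0.00044,0.00005,11.36,92.59
BTB,mg/L,14,(R+G+B)/B,-0.00268,0.00016,5.97,46.79
BTB,mg/L,15,R/G,-0.00139,0.00006,4.32,27.59
BTB,mg/L,16,G/B,-0.00072,0.00005,6.94,73.65
BTB,mg/L,17,R/B,-0.00196,0.00008,4.08,40.45
BTB,mg/L,18,ED,0.740,0.007,0.95,9.49
BTB,mg/L,19,-log(RGB/R0G0B0),0.00294,0.00008,2.72,23.13
Zn,mmol/L,2,G,-78.65,1.27,1.61,0.12
Zn,mmol/L,4,(R+G+B)/3,-32.20,1.58,4.91,0.15
Zn,mmol/L,6,log(G0/G),0.241,0.007,2.90,0.12
Zn,mmol/L,9,G0-G,78.75,0.99,1.26,0.12
Zn,mmol/L,11,dR+dG+dB,82.14,4.24,5.16,0.16
Zn,mmol/L,12,(R+G+B)/R,-0.341,0.031,9.09,0.25
Zn,mmol/L,13,(R+G+B)/G,1.172,0.106,9.01,0.21
Zn,mmol/L,15,R/G,0.747,0.059,7.90,0.13
Zn,mmol/L,16,G/B,-0.903,0.077,8.53,0.22
Zn,mmol/L,18,ED,77.482,0.689,0.89,0.09
Zn,mmol/L,19,-log(RGB/R0G0B0),0.243,0.016,6.58,0.17
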