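analyte,unit,c_low,c_high,method_id,label,s_low,u_low,s_high,u_high,ratio
BTB,mg/L,60,65,1,R,186.07,3.41,183.10,3.27,0.89
BTB,mg/L,60,65,2,G,206.16,1.62,204.23,1.56,1.21
BTB,mg/L,60,65,3,B,216.87,1.54,215.87,1.69,0.62
BTB,mg/L,60,65,4,(R+G+B)/3,202.77,1.19,200.71,1.16,1.75
BTB,mg/L,60,65,5,log(R0/R),0.097,0.004,0.105,0.004,2
BTB,mg/L,60,65,6,log(G0/G),0.041,0.005,0.046,0.005,1
BTB,mg/L,60,65,7,log(B0/B),0.020,0.003,0.022,0.004,0.57
BTB,mg/L,60,65,8,R0-R,43.96,3.39,46.93,3.25,0.89
BTB,mg/L,60,65,9,G0-G,19.89,1.62,21.82,1.57,1.21
BTB,mg/L,60,65,10,B0-B,10.00,1.41,11.07,1.55,0.72
BTB,mg/L,60,65,11,dR+dG+dB,73.98,2.19,80.17,2.12,2.87
BTB,mg/L,60,65,12,(R+G+B)/R,3.307,0.006,3.333,0.006,4.33
BTB,mg/L,60,65,13,(R+G+B)/G,2.942,0.006,2.939,0.006,0.50
BTB,mg/L,60,65,14,(R+G+B)/B,2.797,0.014,2.784,0.013,0.96
BTB,mg/L,60,65,15,R/G,0.892,0.003,0.885,0.003,2.33
BTB,mg/L,60,65,16,G/B,0.948,0.007,0.945,0.006,0.46
BTB,mg/L,60,65,17,R/B,0.849,0.009,0.839,0.009,1.11
BTB,mg/L,60,65,18,ED,50.54,1.09,54.24,1.09,3.39
BTB,mg/L,60,65,19,-log(RGB/R0G0B0),0.16,0.01,0.18,0.01,2
Zn,mmol/L,0.30,0.35,2,G,169.63,2.14,165.70,1.99,1.90
Zn,mmol/L,0.30,0.35,4,(R+G+B)/3,165.00,1.41,163.39,1.31,1.18
Zn,mmol/L,0.30,0.35,6,log(G0/G),0.063,0.01,0.075,0.01,1.20
Zn,mmol/L,0.30,0.35,9,G0-G,25.84,1.70,29.77,1.57,2.40
Zn,mmol/L,0.30,0.35,11,dR+dG+dB,29.02,4.4,33.13,4.19,0.96
Zn,mmol/L,0.30,0.35,12,(R+G+B)/R,2.13,0.03,2.11,0.02,0.80
Zn,mmol/L,0.30,0.35,13,(R+G+B)/G,2.95,0.09,3.01,0.09,0.67
Zn,mmol/L,0.30,0.35,15,R/G,1.40,0.03,1.43,0.02,1.20
Zn,mmol/L,0.30,0.35,16,G/B,1.87,0.09,1.83,0.09,0.44
Zn,mmol/L,0.30,0.35,18,ED,26.91,0.94,30.79,0.88,4.26
Zn,mmol/L,0.30,0.35,19,-log(RGB/R0G0B0),0.079,0.015,0.091,0.015,0.80
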