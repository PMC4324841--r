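location,scenario,period,mean,se,sig
Bhubaneswar,BL,1975,28.35,0.00,
Junagadh,BL,1975,35.87,0.00,
Jalgaon,BL,1975,35.85,0.00,
Raichur,BL,1975,30.45,0.00,
Tirupathi,BL,1975,29.66,0.00,
Vridhachalam,BL,1975,34.02,0.00,
Bhubaneswar,A2,2020,24.90,2.89,*
Junagadh,A2,2020,29.58,0.58,*
Jalgaon,A2,2020,28.92,1.20,*
Raichur,A2,2020,29.49,0.37,*
Tirupathi,A2,2020,27.00,0.36,*
Vridhachalam,A2,2020,25.18,0.21,*
Bhubaneswar,A2,2050,26.47,0.40,*
Junagadh,A2,2050,27.63,0.93,*
Jalgaon,A2,2050,32.43,0.87,*
Raichur,A2,2050,28.01,0.71,*
Tirupathi,A2,2050,26.35,0.53,*
Vridhachalam,A2,2050,25.04,0.49,*
Bhubaneswar,A2,2080,24.88,0.69,*
Junagadh,A2,2080,25.94,1.29,*
Jalgaon,A2,2080,29.65,0.47,*
Raichur,A2,2080,26.09,0.73,*
Tirupathi,A2,2080,24.66,0.79,*
Vridhachalam,A2,2080,23.55,0.54,*
Bhubaneswar,A1B,2020,27.22,0.29,*
Junagadh,A1B,2020,32.05,4.81,*
Jalgaon,A1B,2020,27.65,2.30,*
Raichur,A1B,2020,29.28,0.45,*
Tirupathi,A1B,2020,28.67,1.29,*
Vridhachalam,A1B,2020,29.02,2.64,*
Bhubaneswar,A1B,2050,26.30,0.42,*
Junagadh,A1B,2050,27.46,0.81,*
Jalgaon,A1B,2050,32.16,0.63,*
Raichur,A1B,2050,27.68,0.57,*
Tirupathi,A1B,2050,26.22,0.39,*
Vridhachalam,A1B,2050,24.90,0.36,*
Bhubaneswar,A1B,2080,25.12,0.80,*
Junagadh,A1B,2080,26.21,1.52,*
Jalgaon,A1B,2080,29.42,0.49,*
Raichur,A1B,2080,26.15,0.41,*
Tirupathi,A1B,2080,24.97,0.68,*
Vridhachalam,A1B,2080,23.78,0.51,*
Bhubaneswar,B1,2020,25.80,2.57,*
Junagadh,B1,2020,29.80,2.02,*
Jalgaon,B1,2020,28.78,0.64,*
Raichur,B1,2020,29.28,0.34,*
Tirupathi,B1,2020,25.93,0.94,*
Vridhachalam,B1,2020,25.04,0.25,*
Bhubaneswar,B1,2050,26.65,0.37,*
Junagadh,B1,2050,28.21,0.74,*
Jalgaon,B1,2050,32.97,0.35,*
Raichur,B1,2050,28.37,0.52,*
Tirupathi,B1,2050,26.53,0.31,*
Vridhachalam,B1,2050,25.30,0.38,*
Bhubaneswar,B1,2080,26.07,0.57,*
Junagadh,B1,2080,27.28,1.22,*
Jalgaon,B1,2080,31.72,0.63,*
Raichur,B1,2080,27.61,0.57,*
Tirupathi,B1,2080,26.02,0.36,*
Vridhachalam,B1,2080,24.70,0.34,*
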