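location,scenario,period,mean,se,sig
Bhubaneswar,BL,1975,4.66,0.00,
Junagadh,BL,1975,3.71,0.00,
Jalgaon,BL,1975,3.67,0.00,
Raichur,BL,1975,4.38,0.00,
Tirupathi,BL,1975,4.39,0.00,
Vridhachalam,BL,1975,3.88,0.00,
Bhubaneswar,A2,2020,4.81,0.05,*
Junagadh,A2,2020,4.01,0.05,*
Jalgaon,A2,2020,4.59,0.07,*
Raichur,A2,2020,4.51,0.05,*
Tirupathi,A2,2020,4.83,0.05,*
Vridhachalam,A2,2020,5.16,0.05,*
Bhubaneswar,A2,2050,5.00,0.08,*
Junagadh,A2,2050,4.78,0.13,*
Jalgaon,A2,2050,4.11,0.19,*
Raichur,A2,2050,4.75,0.10,*
Tirupathi,A2,2050,5.03,0.10,*
Vridhachalam,A2,2050,5.29,0.09,*
Bhubaneswar,A2,2080,5.33,0.13,*
Junagadh,A2,2080,5.14,0.98,*
Jalgaon,A2,2080,4.47,0.21,*
Raichur,A2,2080,5.12,0.14,*
Tirupathi,A2,2080,5.36,0.15,*
Vridhachalam,A2,2080,5.61,0.14,*
Bhubaneswar,A1B,2020,4.81,0.06,*
Junagadh,A1B,2020,4.06,0.81,*
Jalgaon,A1B,2020,4.85,0.24,*
Raichur,A1B,2020,4.54,0.06,*
Tirupathi,A1B,2020,4.54,0.18,*
Vridhachalam,A1B,2020,4.57,0.37,*
Bhubaneswar,A1B,2050,5.05,0.08,*
Junagadh,A1B,2050,4.82,0.11,*
Jalgaon,A1B,2050,4.11,0.07,*
Raichur,A1B,2050,4.78,0.07,*
Tirupathi,A1B,2050,5.06,0.07,*
Vridhachalam,A1B,2050,5.32,0.07,*
Bhubaneswar,A1B,2080,5.28,0.13,*
Junagadh,A1B,2080,5.07,0.21,*
Jalgaon,A1B,2080,4.50,0.11,*
Raichur,A1B,2080,5.08,0.08,*
Tirupathi,A1B,2080,5.30,0.12,*
Vridhachalam,A1B,2080,5.54,0.10,*
Bhubaneswar,B1,2020,4.82,0.50,*
Junagadh,B1,2020,4.02,0.28,*
Jalgaon,B1,2020,4.60,0.03,*
Raichur,B1,2020,4.54,0.05,*
Tirupathi,B1,2020,4.87,0.05,*
Vridhachalam,B1,2020,5.18,0.05,*
Bhubaneswar,B1,2050,4.96,0.08,*
Junagadh,B1,2050,4.72,0.10,*
Jalgaon,B1,2050,4.03,0.06,*
Raichur,B1,2050,4.70,0.08,*
Tirupathi,B1,2050,4.99,0.08,*
Vridhachalam,B1,2050,5.24,0.07,*
Bhubaneswar,B1,2080,5.09,0.10,*
Junagadh,B1,2080,4.86,0.16,*
Jalgaon,B1,2080,4.18,0.10,*
Raichur,B1,2080,4.83,0.09,*
Tirupathi,B1,2080,5.11,0.06,*
Vridhachalam,B1,2080,5.36,0.06,*
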