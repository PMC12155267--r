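patient,gender,age,body_length_cm,weight_kg,L_cm,d_cm,actual_angle_deg,predicted_angle_deg
1,Male,22,195,94,32,2.1,29.909,28.070
2,Male,19,185,72,32,1.9,27.088,28.268
3,Male,20,170,65,28.5,1.7,27.212,31.782
4,Male,22,187,96,33,2.2,30.378,26.809
5,Female,21,166,65,28.5,1.5,24.036,23.143
6,Female,20,166,55,27.5,1.7,28.192,25.529
7,Female,18,162,53,25.5,1.3,23.287,24.480
8,Female,21,178,66,27.5,2.1,34.734,31.589
9,Male,23,180,74,33.5,2,27.236,29.960
10,Female,20,173,50,26.5,1.8,30.944,26.330
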