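clone,trait,mean,se,letters
CJH 3,hundred_fruit_weight,112.57,0.74,a
CJH 3,fruit_length,2.00,0.04,b
CJH 3,fruit_width,1.57,0.04,c
CJH 3,fruit_aspect_ratio,1.28,0.02,ab
CJH 3,hundred_seed_weight,59.37,0.52,abc
CJH 3,seed_length,1.73,0.00,a
CJH 3,seed_width,0.79,0.03,a
CJH 3,seed_aspect_ratio,2.19,0.02,ab
CJH 3,shelling_percent,61.57,2.13,a
CJH 3,seed_oil_content,27.93,0.00,b
CJH 3,kernel_oil_content,54.80,0.80,a
CJH 5,hundred_fruit_weight,110.68,2.39,a
CJH 5,fruit_length,2.10,0.08,b
CJH 5,fruit_width,1.69,0.01,abc
CJH 5,fruit_aspect_ratio,1.26,0.00,ab
CJH 5,hundred_seed_weight,57.48,0.45,bc
CJH 5,seed_length,1.72,0.06,a
CJH 5,seed_width,0.80,0.00,a
CJH 5,seed_aspect_ratio,2.15,0.05,ab
CJH 5,shelling_percent,61.96,1.24,a
CJH 5,seed_oil_content,34.19,0.37,a
CJH 5,kernel_oil_content,53.60,1.96,a
CJH 9,hundred_fruit_weight,112.66,0.13,a
CJH 9,fruit_length,2.12,0.07,b
CJH 9,fruit_width,1.63,0.05,bc
CJH 9,fruit_aspect_ratio,1.33,0.05,a
CJH 9,hundred_seed_weight,59.46,1.93,abc
CJH 9,seed_length,1.74,0.00,a
CJH 9,seed_width,0.80,0.02,a
CJH 9,seed_aspect_ratio,2.18,0.03,ab
CJH 9,shelling_percent,60.43,2.50,a
CJH 9,seed_oil_content,23.74,0.58,d
CJH 9,kernel_oil_content,43.50,0.17,b
CJH 12,hundred_fruit_weight,114.40,2.32,a
CJH 12,fruit_length,2.05,0.09,b
CJH 12,fruit_width,1.74,0.01,ab
CJH 12,fruit_aspect_ratio,1.18,0.05,b
CJH 12,hundred_seed_weight,61.20,1.46,ab
CJH 12,seed_length,1.68,0.07,a
CJH 12,seed_width,0.78,0.00,a
CJH 12,seed_aspect_ratio,2.17,0.09,ab
CJH 12,shelling_percent,62.22,1.32,a
CJH 12,seed_oil_content,25.76,0.38,c
CJH 12,kernel_oil_content,45.40,2.10,b
CJH 13,hundred_fruit_weight,116.81,4.36,a
CJH 13,fruit_length,2.16,0.02,b
CJH 13,fruit_width,1.78,0.07,ab
CJH 13,fruit_aspect_ratio,1.22,0.05,ab
CJH 13,hundred_seed_weight,63.61,1.70,a
CJH 13,seed_length,1.71,0.02,a
CJH 13,seed_width,0.81,0.03,a
CJH 13,seed_aspect_ratio,2.12,0.07,b
CJH 13,shelling_percent,58.99,0.45,a
CJH 13,seed_oil_content,24.64,0.54,cd
CJH 13,kernel_oil_content,53.20,2.55,a
TNMC 7,hundred_fruit_weight,109.56,2.29,a
TNMC 7,fruit_length,2.37,0.02,a
TNMC 7,fruit_width,1.80,0.05,a
TNMC 7,fruit_aspect_ratio,1.33,0.00,a
TNMC 7,hundred_seed_weight,56.36,1.06,c
TNMC 7,seed_length,1.75,0.06,a
TNMC 7,seed_width,0.75,0.00,a
TNMC 7,seed_aspect_ratio,2.34,0.06,a
TNMC 7,shelling_percent,63.85,0.58,a
TNMC 7,seed_oil_content,21.92,0.62,e
TNMC 7,kernel_oil_content,35.40,0.26,c
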