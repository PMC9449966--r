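clone,property,mean,se,letters
CJH 3,acid_value,5.27,0.05,d
CJH 3,ffa_percent,2.65,0.05,d
CJH 3,saponification,201.40,1.47,a
CJH 3,iodine,107.56,0.03,a
CJH 3,cetane,49.20,0.69,a
CJH 5,acid_value,5.60,0.06,cd
CJH 5,ffa_percent,2.81,0.20,cd
CJH 5,saponification,201.96,6.97,a
CJH 5,iodine,110.59,5.52,a
CJH 5,cetane,48.44,1.27,a
CJH 9,acid_value,6.25,0.15,b
CJH 9,ffa_percent,3.14,0.00,b
CJH 9,saponification,202.24,9.68,a
CJH 9,iodine,114.26,1.72,a
CJH 9,cetane,47.58,0.70,a
CJH 12,acid_value,7.05,0.20,a
CJH 12,ffa_percent,3.54,0.16,a
CJH 12,saponification,203.36,5.35,a
CJH 12,iodine,114.80,3.91,a
CJH 12,cetane,47.31,2.28,a
CJH 13,acid_value,5.78,0.19,c
CJH 13,ffa_percent,2.90,0.02,c
CJH 13,saponification,201.68,3.27,a
CJH 13,iodine,116.64,1.93,a
CJH 13,cetane,47.12,0.18,a
TNMC 7,acid_value,5.18,0.00,d
TNMC 7,ffa_percent,2.60,0.05,d
TNMC 7,saponification,201.12,1.85,a
TNMC 7,iodine,107.74,3.39,a
TNMC 7,cetane,49.20,1.21,a
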