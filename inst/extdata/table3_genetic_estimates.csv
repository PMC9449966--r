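trait,pcv,gcv,heritability,ga_percent_mean
plant_height,6.08,5.83,92.00,11.50
basal_diameter,5.24,4.96,89.00,9.67
sturdiness_quotient,5.18,4.64,80.00,8.56
primary_branches,14.71,14.65,95.00,30.03
secondary_branches,14.45,14.41,95.00,29.59
male_flowers,11.14,11.03,94.00,22.49
female_flowers,9.13,9.09,95.00,18.64
mf_flower_ratio,21.22,21.10,95.00,43.22
fruits_per_bunch,10.78,10.73,95.00,22.01
bunches_per_branch,5.60,5.48,93.00,11.05
seed_yield,16.05,16.00,95.00,32.85
hundred_fruit_weight,2.50,2.23,80.00,4.11
fruit_length,6.41,5.96,86.00,11.41
fruit_width,6.54,4.80,54.00,7.27
fruit_aspect_ratio,6.86,3.80,31.00,4.33
fruit_yield,19.14,19.11,95.00,39.32
hundred_seed_weight,4.72,4.22,80.00,7.77
seed_length,1.88,1.23,43.00,1.67
seed_width,3.80,2.57,46.00,3.60
seed_aspect_ratio,3.84,3.44,80.00,6.35
shelling_percent,3.06,2.55,70.00,4.38
seed_oil_content,16.49,16.39,95.00,33.56
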