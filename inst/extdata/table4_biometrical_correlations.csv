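trait_row,trait_col,level,r,significant
plant_height,basal_diameter,P,0.581,0
plant_height,sturdiness_quotient,P,0.599,0
plant_height,primary_branches,P,0.183,0
plant_height,secondary_branches,P,0.181,0
plant_height,male_flowers,P,-0.598,0
plant_height,female_flowers,P,0.585,0
plant_height,mf_flower_ratio,P,-0.639,0
plant_height,fruits_per_bunch,P,0.536,0
plant_height,bunches_per_branch,P,-0.050,0
plant_height,seed_yield,P,0.149,0
plant_height,basal_diameter,G,0.634,0
plant_height,sturdiness_quotient,G,0.595,0
plant_height,primary_branches,G,0.207,0
plant_height,secondary_branches,G,0.182,0
plant_height,male_flowers,G,-0.647,0
plant_height,female_flowers,G,0.611,0
plant_height,mf_flower_ratio,G,-0.678,0
plant_height,fruits_per_bunch,G,0.558,0
plant_height,bunches_per_branch,G,-0.027,0
plant_height,seed_yield,G,0.161,0
basal_diameter,sturdiness_quotient,P,-0.304,0
basal_diameter,primary_branches,P,0.689,0
basal_diameter,secondary_branches,P,0.557,0
basal_diameter,male_flowers,P,-0.611,0
basal_diameter,female_flowers,P,0.759,1
basal_diameter,mf_flower_ratio,P,-0.713,0
basal_diameter,fruits_per_bunch,P,0.459,0
basal_diameter,bunches_per_branch,P,0.535,0
basal_diameter,seed_yield,P,0.322,0
basal_diameter,sturdiness_quotient,G,-0.244,0
basal_diameter,primary_branches,G,0.729,0
basal_diameter,secondary_branches,G,0.594,0
basal_diameter,male_flowers,G,-0.654,0
basal_diameter,female_flowers,G,0.815,1
basal_diameter,mf_flower_ratio,G,-0.764,1
basal_diameter,fruits_per_bunch,G,0.483,0
basal_diameter,bunches_per_branch,G,0.566,0
basal_diameter,seed_yield,G,0.341,0
sturdiness_quotient,primary_branches,P,-0.456,0
sturdiness_quotient,secondary_branches,P,-0.325,0
sturdiness_quotient,male_flowers,P,-0.095,0
sturdiness_quotient,female_flowers,P,-0.065,0
sturdiness_quotient,mf_flower_ratio,P,-0.041,0
sturdiness_quotient,fruits_per_bunch,P,0.171,0
sturdiness_quotient,bunches_per_branch,P,-0.581,0
sturdiness_quotient,seed_yield,P,-0.144,0
sturdiness_quotient,primary_branches,G,-0.492,0
sturdiness_quotient,secondary_branches,G,-0.378,0
sturdiness_quotient,male_flowers,G,-0.129,0
sturdiness_quotient,female_flowers,G,-0.084,0
sturdiness_quotient,mf_flower_ratio,G,-0.052,0
sturdiness_quotient,fruits_per_bunch,G,0.191,0
sturdiness_quotient,bunches_per_branch,G,-0.621,0
sturdiness_quotient,seed_yield,G,-0.154,0
primary_branches,secondary_branches,P,0.840,1
primary_branches,male_flowers,P,-0.517,0
primary_branches,female_flowers,P,0.373,0
primary_branches,mf_flower_ratio,P,-0.468,0
primary_branches,fruits_per_bunch,P,0.277,0
primary_branches,bunches_per_branch,P,0.864,1
primary_branches,seed_yield,P,0.502,0
primary_branches,secondary_branches,G,0.847,1
primary_branches,male_flowers,G,0.523,0
primary_branches,female_flowers,G,0.381,0
primary_branches,mf_flower_ratio,G,-0.475,0
primary_branches,fruits_per_bunch,G,0.278,0
primary_branches,bunches_per_branch,G,0.883,1
primary_branches,seed_yield,G,0.504,0
secondary_branches,male_flowers,P,-0.433,0
secondary_branches,female_flowers,P,0.467,0
secondary_branches,mf_flower_ratio,P,-0.441,0
secondary_branches,fruits_per_bunch,P,0.227,0
secondary_branches,bunches_per_branch,P,0.726,0
secondary_branches,seed_yield,P,0.494,0
secondary_branches,male_flowers,G,-0.441,0
secondary_branches,female_flowers,G,0.470,0
secondary_branches,mf_flower_ratio,G,-0.446,0
secondary_branches,fruits_per_bunch,G,0.224,0
secondary_branches,bunches_per_branch,G,0.747,1
secondary_branches,seed_yield,G,0.497,0
male_flowers,female_flowers,P,-0.761,1
male_flowers,mf_flower_ratio,P,0.959,1
male_flowers,fruits_per_bunch,P,-0.947,1
male_flowers,bunches_per_branch,P,-0.598,0
male_flowers,seed_yield,P,-0.843,1
male_flowers,female_flowers,G,-0.768,1
male_flowers,mf_flower_ratio,G,0.960,1
male_flowers,fruits_per_bunch,G,-0.960,1
male_flowers,bunches_per_branch,G,-0.631,0
male_flowers,seed_yield,G,-0.852,1
female_flowers,mf_flower_ratio,P,-0.911,1
female_flowers,fruits_per_bunch,P,0.739,1
female_flowers,bunches_per_branch,P,0.419,0
female_flowers,seed_yield,P,0.555,0
female_flowers,mf_flower_ratio,G,-0.914,1
female_flowers,fruits_per_bunch,G,0.745,1
female_flowers,bunches_per_branch,G,0.436,0
female_flowers,seed_yield,G,0.557,0
mf_flower_ratio,fruits_per_bunch,P,-0.922,1
mf_flower_ratio,bunches_per_branch,P,-0.541,0
mf_flower_ratio,seed_yield,P,-0.760,1
mf_flower_ratio,fruits_per_bunch,G,-0.932,1
mf_flower_ratio,bunches_per_branch,G,-0.569,0
mf_flower_ratio,seed_yield,G,-0.765,1
fruits_per_bunch,bunches_per_branch,P,0.476,0
fruits_per_bunch,seed_yield,P,0.845,1
fruits_per_bunch,bunches_per_branch,G,0.487,0
fruits_per_bunch,seed_yield,G,0.850,1
bunches_per_branch,seed_yield,P,0.771,1
bunches_per_branch,seed_yield,G,0.788,1
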