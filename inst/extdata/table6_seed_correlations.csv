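trait_row,trait_col,level,r,significant
hundred_seed_weight,seed_length,P,-0.532,0
hundred_seed_weight,seed_width,P,0.549,0
hundred_seed_weight,seed_aspect_ratio,P,-0.721,1
hundred_seed_weight,shelling_percent,P,-0.651,0
hundred_seed_weight,seed_oil_content,P,-0.155,0
hundred_seed_weight,seed_length,G,-0.599,0
hundred_seed_weight,seed_width,G,0.679,0
hundred_seed_weight,seed_aspect_ratio,G,-0.760,1
hundred_seed_weight,shelling_percent,G,-0.878,1
hundred_seed_weight,seed_oil_content,G,-0.188,0
seed_length,seed_width,P,-0.225,0
seed_length,seed_aspect_ratio,P,0.434,0
seed_length,shelling_percent,P,0.200,0
seed_length,seed_oil_content,P,-0.224,0
seed_length,seed_width,G,-0.280,0
seed_length,seed_aspect_ratio,G,0.732,1
seed_length,shelling_percent,G,0.135,0
seed_length,seed_oil_content,G,-0.341,0
seed_width,seed_aspect_ratio,P,-0.780,1
seed_width,shelling_percent,P,-0.646,0
seed_width,seed_oil_content,P,0.325,0
seed_width,seed_aspect_ratio,G,-0.985,1
seed_width,shelling_percent,G,-0.895,1
seed_width,seed_oil_content,G,0.464,0
seed_aspect_ratio,shelling_percent,P,0.649,0
seed_aspect_ratio,seed_oil_content,P,-0.444,0
seed_aspect_ratio,shelling_percent,G,0.865,1
seed_aspect_ratio,seed_oil_content,G,-0.471,0
shelling_percent,seed_oil_content,P,-0.002,0
shelling_percent,seed_oil_content,G,-0.002,0
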