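trait_row,trait_col,level,r,significant
hundred_fruit_weight,fruit_length,P,-0.408,0
hundred_fruit_weight,fruit_width,P,0.157,0
hundred_fruit_weight,fruit_aspect_ratio,P,-0.540,0
hundred_fruit_weight,fruit_yield,P,0.540,0
hundred_fruit_weight,fruit_length,G,-0.428,0
hundred_fruit_weight,fruit_width,G,0.048,0
hundred_fruit_weight,fruit_aspect_ratio,G,-0.773,1
hundred_fruit_weight,fruit_yield,G,0.605,0
fruit_length,fruit_width,P,0.548,0
fruit_length,fruit_aspect_ratio,P,0.342,0
fruit_length,fruit_yield,P,-0.672,0
fruit_length,fruit_width,G,0.800,1
fruit_length,fruit_aspect_ratio,G,0.563,0
fruit_length,fruit_yield,G,-0.720,1
fruit_width,fruit_aspect_ratio,P,-0.454,0
fruit_width,fruit_yield,P,-0.144,0
fruit_width,fruit_aspect_ratio,G,-0.159,0
fruit_width,fruit_yield,G,-0.205,0
fruit_aspect_ratio,fruit_yield,P,-0.459,0
fruit_aspect_ratio,fruit_yield,G,-0.838,1
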