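standard,property,limit,direction
IS 15607,cetane,51,min
ASTM D6751,cetane,47,min
EN 14214,iodine,115,max
IS 15607,acid_value,0.5,max
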