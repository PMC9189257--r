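"variable","mean","sd"
"VIQ",102,18
"Occ",0.2,0.4
"Educ",0.4,0.49
"Eth",0.39,0.488
"Inter",0.25,0.433
"Ment",0.4,0.49
"Fam",0.18,0.384
"Life",0.25,0.433
"Pers",0.25,0.433
"Sup",0.25,0.433
"Anx",0.25,0.433
"n",215,NA
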