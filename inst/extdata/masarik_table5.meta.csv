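"variable","mean","sd"
"THost",3.486,1.652
"PHost",3.63,1.426
"GTotal",4.381,1.392
"GDom",3.192,0.869
"GRec",1.189,0.869
"n",281,NA
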