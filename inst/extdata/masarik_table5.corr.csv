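"variable","THost","PHost","GTotal","GDom","GRec"
"THost",1,0.28,-0.046,-0.06,-0.015
"PHost",0.28,1,-0.024,-0.111,0.073
"GTotal",-0.046,-0.024,1,0.807,0.802
"GDom",-0.06,-0.111,0.807,1,0.295
"GRec",-0.015,0.073,0.802,0.295,1
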