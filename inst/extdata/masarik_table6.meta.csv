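"variable","mean","sd"
"ANKK1d",0.342,0.475
"DRD4d",0.359,0.481
"DATd",0.925,0.263
"HTT5d",0.754,0.431
"COMTd",0.811,0.392
"ANKK1r",0.039,0.194
"DRD4r",0.018,0.132
"DATr",0.559,0.497
"HTT5r",0.228,0.42
"COMTr",0.345,0.476
"n",281,NA
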