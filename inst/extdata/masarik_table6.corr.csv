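"variable","ANKK1d","DRD4d","DATd","HTT5d","COMTd","ANKK1r","DRD4r","DATr","HTT5r","COMTr"
"ANKK1d",1,-0.149,0.005,0.045,0.002,0.28,-0.097,0.036,0.092,-0.034
"DRD4d",-0.149,1,0.015,-0.09,-0.075,-0.036,0.18,-0.036,-0.018,0.033
"DATd",0.005,0.015,1,0.089,0.001,-0.012,-0.064,0.32,0.09,-0.05
"HTT5d",0.045,-0.09,0.089,1,-0.064,-0.013,0.014,0.092,0.31,0.032
"COMTd",0.002,-0.075,0.001,-0.064,1,0.05,-0.004,-0.007,-0.085,0.35
"ANKK1r",0.28,-0.036,-0.012,-0.013,0.05,1,-0.027,-0.005,0.065,0.046
"DRD4r",-0.097,0.18,-0.064,0.014,-0.004,-0.027,1,0.065,-0.073,0.016
"DATr",0.036,-0.036,0.32,0.092,-0.007,-0.005,0.065,1,0.038,0.027
"HTT5r",0.092,-0.018,0.09,0.31,-0.085,0.065,-0.073,0.038,1,-0.037
"COMTr",-0.034,0.033,-0.05,0.032,0.35,0.046,0.016,0.027,-0.037,1
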