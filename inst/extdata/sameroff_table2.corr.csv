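"variable","VIQ","Occ","Educ","Eth","Inter","Ment","Fam","Life","Pers","Sup","Anx"
"VIQ",1,-0.59,-0.56,-0.51,-0.39,-0.16,-0.36,-0.26,-0.5,-0.3,-0.24
"Occ",-0.59,1,0.62,0.53,0.22,0.25,0.31,0.21,0.53,0.33,0.32
"Educ",-0.56,0.62,1,0.49,0.21,0.28,0.39,0.22,0.54,0.3,0.24
"Eth",-0.51,0.53,0.49,1,0.15,-0.03,0.25,0.04,0.57,0.38,0.11
"Inter",-0.39,0.22,0.21,0.15,1,0.17,0.34,0.17,0.17,0.14,0.14
"Ment",-0.16,0.25,0.28,-0.03,0.17,1,0.26,0.25,0.09,0.19,0.49
"Fam",-0.36,0.31,0.39,0.25,0.34,0.26,1,0.25,0.34,0.19,0.15
"Life",-0.26,0.21,0.22,0.04,0.17,0.25,0.25,1,0.22,0.08,0.28
"Pers",-0.5,0.53,0.54,0.57,0.17,0.09,0.34,0.22,1,0.18,0.13
"Sup",-0.3,0.33,0.3,0.38,0.14,0.19,0.19,0.08,0.18,1,0.23
"Anx",-0.24,0.32,0.24,0.11,0.14,0.49,0.15,0.28,0.13,0.23,1
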