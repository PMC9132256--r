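arm,state,p_serious,p_nonserious,serious_supplemental,serious_surgery,nonserious_supplemental,nonserious_surgery
TLIF,Minimal,0.0112,0.0787,1.0000,0.0000,0.9286,0.0714
TLIF,Moderate,0.0000,0.0286,0.0000,0.0000,1.0000,0.0000
TLIF,Severe,0.1304,0.0435,0.6667,0.3333,1.0000,0.0000
TLIF,Crippled,0.1111,0.1667,0.5000,0.5000,1.0000,0.0000
TLIF,Bedbound,0.2500,0.2500,1.0000,0.0000,1.0000,0.0000
TOPS,Minimal,0.0200,0.0400,0.7778,0.2222,0.9444,0.0556
TOPS,Moderate,0.0235,0.0353,0.0050,0.0050,1.0000,0.0000
TOPS,Severe,0.0256,0.2051,1.0000,0.0000,1.0000,0.0000
TOPS,Crippled,0.2667,0.3333,0.6250,0.3750,1.0000,0.0000
TOPS,Bedbound,0.0000,1.0000,0.0000,0.0000,1.0000,0.0000
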