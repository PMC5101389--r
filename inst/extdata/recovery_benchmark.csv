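compound,role,level,conc_ug_ml,level_percent,recovery,rsd
moxonidine,API,80,80,80,99.04,1.85
moxonidine,API,100,100,100,101.15,0.45
moxonidine,API,120,120,120,101.54,0.32
impA,impurity,LOQ,0.04,0.04,95.89,3.79
impA,impurity,100,0.5,0.5,101.22,0.35
impA,impurity,120,0.6,0.6,100.51,0.88
impB,impurity,LOQ,0.04,0.04,97.65,2.92
impB,impurity,100,0.5,0.5,101.28,0.27
impB,impurity,120,0.6,0.6,99.19,0.85
impC,impurity,LOQ,0.08,0.08,95.95,2.02
impC,impurity,100,1.0,1.0,114.08,0.27
impC,impurity,120,1.2,1.2,93.82,1.48
impD,impurity,LOQ,0.08,0.08,93.66,2.09
impD,impurity,100,1.0,1.0,100.83,0.83
impD,impurity,120,1.2,1.2,97.77,0.39
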