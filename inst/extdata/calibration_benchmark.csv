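compound,range_low,range_high,slope,intercept,r,t,t_tab
moxonidine,25,150,29142.47,94.864,0.9992,1.1968,2.365
impA,0.04,0.6,24.45681,-0.09526,0.9991,0.0607,2.262
impB,0.04,0.6,27.659,0.1724,0.9976,0.5319,2.262
impC,0.08,1.2,18.18141,0.1283,0.9982,0.4016,2.262
impD,0.08,1.2,11.82117,0.1404,0.9976,0.5762,2.262
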