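name,cas,activity,p0,p1,significance,confidence_pct
Isethionic acid,107-36-8,0,0.750,0.003,0.997,75.0
Phenethyl benzoate,94-47-3,0,0.744,0.004,0.996,74.4
Phosphonic acid,1660-95-3,0,0.727,0.004,0.996,72.7
Reaction mass of cis- and trans-4-(isopropyl)cyclohexanemethanol,5502-75-0,0,0.424,0.022,0.978,42.4
Sodium cocoyl glycinate,90387-74-9,0,0.397,0.023,0.978,39.7
N-[2-[(2-chloro-4-6-dinitrophenyl)azo]-5-(diethylamino)phenyl]acetamide,66557-45-7,0,0.355,0.022,0.978,35.5
2-Chloro-1-(4-chlorophenyl)propan-1-one,877-38-3,1,0.002,0.836,0.998,83.6
(R)-6-(isopropyl)-3-methylcyclohex-2-en-1-one,4573-50-6,1,0.002,0.800,0.998,80.0
2-Ethylhexylamine,104-75-6,1,0.002,0.792,0.998,79.2
4-Chloro-N-methylpyridine-2-carboxamide hydrochloride (1:1),882167-77-3,1,0.013,0.560,0.987,56.0
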