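name,cas,activity,similarity
2-5-Diaminotoluene sulphate,615-50-9,0,0.394
2-4-Xylidine,95-68-1,0,0.393
1-2-4-Trichloro-5-methylbenzene,23503-68-6,0,0.363
Citronellyl butyrate,141-16-2,0,0.356
2-Ethenylpyridine,100-69-6,0,0.282
Methyl dihydrojasmonate,24851-98-7,0,0.236
(1S-2R-5S)-5-methyl-2-(1-methylethyl)cyclohexanol,15356-60-2,0,0.175
Propargyl bromide,106-96-7,0,0.080
1-2-3-5-Tetrachlorobenzene,634-90-2,1,0.906
Nonafluorovaleric acid,2706-90-3,1,0.877
2-3-5-Trichlorophenol,933-78-8,1,0.876
Phenanthrene,85-01-8,1,0.861
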