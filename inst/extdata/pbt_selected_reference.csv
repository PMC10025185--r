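name,cas,activity,p0,p1,significance,confidence_pct
2-Methylallyl alcohol,513-42-8,0,0.910,0.003,0.997,91.0
Polymethacrylic acid,25087-26-7,0,0.854,0.003,0.997,85.4
N-Isopropylacrylamide,2210-25-5,0,0.849,0.003,0.997,84.9
Nitrobenzene,98-95-3,0,0.813,0.003,0.997,81.3
Polyurethane,9009-54-5,0,0.709,0.003,0.997,70.9
2-2'-(Vinylenedi-p-phenylene)bisbenzoxazole,1533-45-5,0,0.216,0.033,0.968,21.6
2-Naphthalenecarboxamide N-(5-chloro-2-methylphenyl)-3-hydroxy-,135-63-7,0,0.208,0.036,0.964,20.8
Methyl cinnamate,103-26-4,0,0.201,0.033,0.967,20.1
(1a-2a-3a-4b-5a-6b)-1-2-3-4-5-6-Hexachlorocyclohexane,319-86-8,1,0.007,0.845,0.993,84.5
1-2-3-5-Tetrachlorobenzene,634-90-2,1,0.013,0.718,0.987,71.8
1-2-3-4-5-Pentachlorobenzene,608-93-5,1,0.004,0.693,0.996,69.3
2-3-5-Trichlorophenol,933-78-8,1,0.023,0.244,0.977,24.4
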