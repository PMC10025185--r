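source,hazard_code,endpoint
*,H340,CMR
*,H341,CMR
*,H350,CMR
*,H350i,CMR
*,H351,CMR
*,H360,CMR
*,H360D,CMR
*,H360F,CMR
*,H360FD,CMR
*,H361,CMR
*,H361d,CMR
*,H361f,CMR
*,H362,CMR
*,ED_assessment_list,ED
*,PBT_Annex_XIII,PBT
*,vPvB_Annex_XIII,vPvB
*,CMR,CMR
*,ED,ED
*,PBT,PBT
*,vPvB,vPvB
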