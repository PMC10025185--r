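endpoint,quantity,count
CMR,before_yes,1362
CMR,before_no,477
CMR,before_pending,39
CMR,before_noinformation,2756
CMR,predicted_total,3312
CMR,predicted_positive,1423
CMR,predicted_uncertain,1076
CMR,predicted_negative,813
CMR,new_positive,691
CMR,new_negative,505
CMR,new_highconf_positive,119
CMR,new_highconf_negative,3
PBT,before_yes,38
PBT,before_no,357
PBT,before_pending,0
PBT,before_noinformation,4239
PBT,predicted_total,3312
PBT,predicted_positive,121
PBT,predicted_uncertain,392
PBT,predicted_negative,2799
PBT,new_positive,85
PBT,new_negative,2575
PBT,new_highconf_positive,0
PBT,new_highconf_negative,47
vPvB,before_yes,43
vPvB,before_no,357
vPvB,before_pending,0
vPvB,before_noinformation,4234
vPvB,predicted_total,3312
vPvB,predicted_positive,110
vPvB,predicted_uncertain,424
vPvB,predicted_negative,2778
vPvB,new_positive,72
vPvB,new_negative,2555
vPvB,new_highconf_positive,3
vPvB,new_highconf_negative,29
GLOBAL,n_compounds,4634
GLOBAL,annotated_after_all,9156
GLOBAL,annotated_after_highconf,3037
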