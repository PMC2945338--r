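stratum,ref_change,ref_stable_forest,ref_stable_nonforest,n,mapped_area_ha
change,51,23,13,87,22044
stable_forest,0,416,15,431,2694787
stable_nonforest,1,20,410,431,4071576
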