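# Forest systems and forest-type classes of the studied floodplain with
# annual flooding period and extents (ha) from the regional habitat map.
# units: ha
# The source's printed "Sum of hectares" row (251,400 / 436,295 / 30,173)
# carries a column-header misalignment; totals here are recomputed from the
# entries (unprotected entries sum to 30,171 vs the reported 30,173).
system,type,flooding,total_ha,protected_ha,unprotected_ha
mangrove,beach_forest,tidal,5327,4672,655
mangrove,mangrove_forest,tidal,12863,12357,506
mangrove,nipah_palm_forest,tidal,26618,25399,1219
mangrove,transitional_forest,semi_tidal,13849,10567,3282
seasonally_flooded,freshwater_swamp_forest,gt6_months,22284,16721,5563
seasonally_flooded,seasonal_freshwater_swamp_forest,3_6_months,12501,8253,4248
seasonally_flooded,peat_swamp_forest,gt6_months,2132,2102,30
seasonally_flooded,swamp,gt9_months,2750,2048,702
lowland_dry,lowland_dry_forest,lt3_months,39008,30693,8315
lowland_dry,lowland_dry_dipterocarp_forest,never_rarely,101878,100866,1012
lowland_dry,limestone_forest,never_rarely,1679,1392,287
mixed_degraded,severely_degraded,varied,10511,6159,4352
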