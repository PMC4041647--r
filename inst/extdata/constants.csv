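# Region-level scalar areas used by the headline accounting.
# units: ha
# predicted_unsuitable_forest is the reported mangrove + seasonally
# flooded unprotected extent (16,207 ha); summing the table1 columns gives
# 16,205 ha, a known 2-ha discrepancy in the source.
name,value_ha
study_region,520269
oil_palm_total,250617
unprotected_forest,30173
existing_redundant_oil_palm,15810
predicted_unsuitable_forest,16207
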