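# Land-title types over the unprotected forest: extent and number of
# unique demarcated titles.
# units: ha
# Reported TOTAL row: 30,173 ha over 1,338 titles (entries sum to 30,175).
title,area_ha,n_titles
NT,9497,1175
CL,9732,163
state_demarcated,3937,104
state_undemarcated,7009,NA
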