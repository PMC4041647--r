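# Land-title extent (ha) of the existing oil-palm age and productivity
# classes across the full study region.
# units: ha
# Reported row totals: 3,290 / 4,030 / 191,832 / 28,081 / 7,575 / 15,810;
# reported column totals 70,945 / 174,698 / 4,974; grand total 250,617
# (cells sum to 250,619; 1-2 ha rounding discrepancies in the source).
class,NT,CL,state_or_undemarcated
cleared,1729,1218,343
planted_out,960,2520,550
young_prime_full,49328,140157,2347
up75,10959,16563,560
up50,3489,3754,332
up25,4481,10486,843
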