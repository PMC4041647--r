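# Annualized NPV class endpoints (USD/ha/yr) of the regional oil-palm
# cash-flow models at an 11% discount rate; capacities are the nominal
# class-boundary fractions of the 136-SPH full planting density.
# units: USD/ha/yr
class,capacity,npv_usd_ha_yr
full_stand,1.00,637
full_stand,0.76,413
up75,0.75,403
up75,0.51,179
up50,0.50,169
up50,0.26,-55
up25,0.25,-65
up25,0.00,-299
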