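# Pipeline configuration for the durum-wheat drought screen.
# Days are in DAS (days after sowing); stress is imposed at 104 DAS.
input_dir: wheat_ssd_data
output_dir: wheat_ssd_out
t0: 55                 # WUE reference day (imaging start)
control_treatment: control
db_config: {logBase: natural, topDivisor: 3, zeroTopPolicy: omit_term}
seg_params: {threshold: otsu, minComponentPx: 25, openingRadius: 1}
water_mode: evapotranspiration   # no bare pots in this trial
mrt_day: 139
compare: treatment
seed: 7
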