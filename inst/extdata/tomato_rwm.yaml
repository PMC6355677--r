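# Pipeline configuration for the tomato reduced-water-management trial.
# Days are in DAT (days after treatment start); all arms at 70% field
# capacity, ten bare-soil pots provide the evaporation baseline.
input_dir: tomato_rwm_data
output_dir: tomato_rwm_out
t0: 0
db_config: {logBase: natural, topDivisor: 3, zeroTopPolicy: omit_term}
seg_params: {threshold: otsu, minComponentPx: 25, openingRadius: 1}
water_mode: subtract_evap
mrt_day: 14
compare: genotype
control_arm: UTC70
seed: 7
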