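# Per-dish flour niche choice of flour beetles: 3 individuals per dish
# observed at 14 time points; availability differs by life stage (larvae
# burrow and are mostly scorable, only ~33.4% of adults are on their feet).
archetype: dish_proportion
n_labs: 3
units_per_group_per_lab: 18
alpha: -0.13
beta: -0.41
lab_intercept_sd: 0.25
lab_slope_sd: 0.0
unit_re_sd: 0.5
olre_sd: 0.5
residual_sd: 1.0
n_timepoints: 14
availability_prob: [0.9, 0.334]
response_ceiling: Inf
transform: none
group_size: 3
treatment_levels: [larvae, adult]
outcome_id: niche_choice
seed: 1
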