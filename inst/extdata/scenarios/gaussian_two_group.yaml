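# Two-group continuous-response design: post-contact immobility duration
# of sawfly larvae under a starvation treatment, generated on the
# log(y + 1) scale and truncated at the 600 s observation ceiling.
archetype: gaussian_two_group
n_labs: 3
units_per_group_per_lab: 30
alpha: 3.9
beta: -1.67
lab_intercept_sd: 0.35
lab_slope_sd: 0.0
unit_re_sd: 0.0
olre_sd: 0.0
residual_sd: 1.2
n_timepoints: 1
availability_prob: 1.0
response_ceiling: 600
transform: log1p
group_size: 3
treatment_levels: [control, starved]
outcome_id: pci_duration
seed: 1
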