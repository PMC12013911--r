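lab_id,outcome_id,pooled,estimate,se,ci_low,ci_high,p_value
Overall,pci_duration,TRUE,-1.67,0.62,-2.88,-0.46,0.01
Lab A,pci_duration,FALSE,-2.70,0.20,-3.1,-2.29,<0.001
Lab B,pci_duration,FALSE,-0.81,0.55,-1.89,0.28,0.15
Lab C,pci_duration,FALSE,-1.17,0.47,-2.09,-0.25,0.02
Overall,distance_moved,TRUE,3.43,0.72,2.01,4.84,<0.001
Lab A,distance_moved,FALSE,4.01,0.48,3.07,4.95,<0.001
Lab B,distance_moved,FALSE,1.87,0.77,0.36,3.39,0.02
Lab C,distance_moved,FALSE,4.25,0.72,2.83,5.66,<0.001
Overall,substrate_choice,TRUE,0.15,0.26,-0.36,0.66,0.58
Lab A,substrate_choice,FALSE,0.34,0.24,-0.13,0.82,0.16
Lab B,substrate_choice,FALSE,-0.04,0.20,-0.44,0.36,0.83
Lab C,substrate_choice,FALSE,0.17,0.17,-0.18,0.51,0.34
Overall,niche_choice,TRUE,-0.41,0.21,-0.78,-0.00,0.05
Lab A,niche_choice,FALSE,-0.48,0.18,-0.84,-0.12,0.01
Lab B,niche_choice,FALSE,-0.16,0.09,-0.33,0.01,0.06
Lab C,niche_choice,FALSE,-0.82,0.16,-1.13,-0.5,<0.001
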