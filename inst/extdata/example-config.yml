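# example simulation configuration for the rvth CLI
# (keys mirror sim_config() and wright_params() arguments)
n_cases: 1000
n_controls: 1000
prevalence: 0.1
rsq: 0.15
delta: 0.5
zeta: 0.8
cds_length: 1209
scenario: linear
maf_upper: 0.005
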