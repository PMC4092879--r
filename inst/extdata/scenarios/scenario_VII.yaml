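name: "VII"
n_per_group: 2
prop_de: 0.10
up: 1
down: 1
fc_lower_bound: 1.1
depth_lower_bound: 1
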