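# Example scenario: growth-ratio 1.6 surge with all reference defaults.
# Any omitted key falls back to the built-in calibration (mixes, path
# table, capacities, service-time distributions, 278 AL3-AL5/day).
name: GR2-example
growth_ratio: 1.6
replications: 300
seed: 1
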