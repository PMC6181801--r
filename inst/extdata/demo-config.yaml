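# Scaled-down demonstration configuration for run_pipeline().
n_subjects: 6
n_components: 2
n_volumes: 60
n_boot: 200
seed: 7
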