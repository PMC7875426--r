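# Small dense network for fast end-to-end exercises.
p: 8
density: 0.15
lag: 2
n_times: 12
n_reps: 3
noise_sd: 0.2
seed: 2
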