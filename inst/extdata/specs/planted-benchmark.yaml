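# Desk-scale planted benchmark: the package's reference recovery conditions.
p: 15
density: 0.05
lag: 2
n_times: 21
n_reps: 10
noise_sd: 0.2
seed: 1
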