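# Lag-1 process: exercises the degenerate lag-choice path.
p: 10
density: 0.08
lag: 1
n_times: 15
n_reps: 4
noise_sd: 0.3
seed: 3
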