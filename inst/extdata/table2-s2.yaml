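# Swapped-rate benchmark configuration (c = 1, e = 1/16, i = 1/4).
preset: table2-s2
n_reps: 1000
seed: 20190612
grid_dt: 0.25
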