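# Benchmark configuration: main rate preset (c = 1, e = 1/4, i = 1/16),
# group size 400, four reference initial conditions supplied by the preset.
preset: table2-main
n_reps: 1000
seed: 20190612
grid_dt: 0.25
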