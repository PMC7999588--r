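# Example fallwatch pipeline configuration (scaled-down day for quick runs;
# the emulated protocol uses day_duration: 28800).
n_subjects: 30
n_low_risk: 9
frame_rate: 30
day_duration: 900
separation_mode: separable
n_incongruent: 0
noise_sd: 0
algorithms: [KNN, NB, NN]
max_combo: 2
n_boot: 10000
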