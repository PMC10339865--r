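# Example pipeline configuration: four simulated pens observed for six
# hours, 20-minute image sampling, 5-minute velocity windows.
out_dir: recumbency-run
n_pens: 4
duration_s: 21600
state_period_s: 1800
frame_interval_s: 1
sampling_interval_s: 1200
n_animals: 18
window_s: 300
blur_cutoff: 1000
blur_sigmas: [0.0, 0.5, 1.0, 2.0, 4.0]
image_size_px: [64, 64]
disagreement_rate: 0.025
method: exhaustive
k: 10
seed: 123
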