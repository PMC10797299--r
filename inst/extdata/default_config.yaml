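# Default synthetic-study configuration for the ensembleatlas pipeline.
# Any key of synth_config() can be set here; unknown keys are rejected.
n_cells: 500
pattern: poisson
cluster_rate: 60
cluster_sd: 0.05
ventral_gradient: 0
n_mice_per_group: 6
counts_per_mouse: 4000
starter_mean: 150
image_size: 256
pixel_size_mm: 0.002
cell_radius_px: 4
blobs_per_image: 12
axon_area_px: 500
background_mean: 20
background_sd: 2
signal_amplitude: 100
sampling_rate_hz: 100
transient_amplitude: 0.1
transient_tau_s: 2
photometry_noise_sd: 0.005
event_times_s: [30, 55, 80, 105]
seed: 1
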