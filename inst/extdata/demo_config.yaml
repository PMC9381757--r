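# Demo configuration: a small end-to-end synthetic run exercising every
# pipeline stage. See default_pipeline_config() for all keys and defaults.
seed: 20220816
stages: [simulate, pcc, foci, satellite, quantify]
simulate:
  n_example_images: 1
  write_tiff: true
pcc:
  n_nuclei_per_mode: 12
  marker_name: H3K27me3
  noise_sd: 600
  half_length_um: 2.5
foci:
  n_nuclei: 20
satellite:
  n_reads: 2000
  satellite_fraction: 0.1
  methylation_rate: 0.8
quantify:
  n_per_group: 10
  amplitude_ratio: 0.24
  xi_ratio: 0.35
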