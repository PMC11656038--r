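# Demonstration pipeline configuration: a small synthetic vigilance-task
# cohort analysed end to end. Sample rate 125 Hz keeps the dyadic scales
# (2^j * 8 ms) aligned with the millisecond scale labels.
seed: 20
synthetic:
  task: PVT
  n_participants: 3
  sample_rate: 125
trend:
  windows_s: [5, 10]
  conservative: {window_s: 10, span_s: 14}
  scales_ms: [8192, 16384]
  max_interp_frac: 0.5
analysis:
  schemes: [mean_split]
  alpha_level: 0.05
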