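# Full-scale curtain profile; pass via `fishcurtain --config`.
n_beams: 40
beam_spacing_cm: 1.5
array_gap_cm: 6.0
sampling_rate_hz: 50
height_filter_threshold_cm: 1.5
upstream_label: A
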