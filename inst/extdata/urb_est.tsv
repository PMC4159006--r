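group	with_est	without_est
no_virilis_homolog	53	11
virilis_homolog	786	83
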