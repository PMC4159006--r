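category	observed	expected	total
human_all	104	400.2	933
human_testis_specific	15	27.9	298
human_other	80	270.0	544
mosquito_all	506	719.9	933
mosquito_testis_specific	129	143.0	298
mosquito_other	343	451.6	544
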