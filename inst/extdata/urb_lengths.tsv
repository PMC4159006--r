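group	n	mean
ur_all	933	477
ur_human_homolog	104	1114
adjacent_all	891	510.5
adjacent_human_homolog	NA	595
ur_expression_annotated	842	NA
ur_longest_protein	1	22971
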