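row	length_bp	snp_baizhima	rate_snp_baizhima	snp_mishuozhima	rate_snp_mishuozhima	indel_baizhima	rate_indel_baizhima	indel_mishuozhima	rate_indel_mishuozhima
Average	14576399	61870.63	3.89	59452.31	3.81	22634.81	1.44	21709.94	1.40
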