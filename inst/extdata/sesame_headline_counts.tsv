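quantity	value
union_snps	1332025
union_indels	506245
shared_snps	609178
shared_indels	203271
coding_snps	70018
coding_indels	8311
synonymous_snps	33385
nonsynonymous_snps	36633
positive_selected_genes	2274
rapid_divergence_genes	886
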