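location	snp_baizhima	snp_mishuozhima	indel_baizhima	indel_mishuozhima
UTR5	8976	9064	3110	3124
CDS	51326	51550	5594	5897
UTR3	8677	9245	2564	2724
Intron	92710	94795	27022	27547
mRNA	161689	164654	38290	39292
Intergenic	828241	786583	323867	308067
Total	989930	951237	362157	347359
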