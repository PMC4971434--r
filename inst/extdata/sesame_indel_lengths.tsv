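indel_bp	baizhima	mishuozhima
1	43771	45022
2	23096	23654
3	11852	12105
4	13026	13017
5	11501	12024
6	8311	8365
7	7612	7795
8	8531	8663
9	8625	8851
10	7666	7698
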