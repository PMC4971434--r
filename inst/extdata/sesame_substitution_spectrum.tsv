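substitution	baizhima	mishuozhima
G>C	35865	34549
C>G	36187	34810
T>G	42004	40487
A>C	42001	40580
C>A	42432	40911
G>T	42753	41194
A>T	53026	51056
T>A	53303	51326
T>C	158750	151978
A>G	159231	153484
G>A	161805	155200
C>T	162568	155655
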