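#alphabet=2
#maxlen=4
0	1.0
00	3.0
01	4.0
000	4.5
001	5.5
010	5.5
011	5.5
0000	5.0
0001	7.0
0010	7.0
0011	7.0
0100	7.0
0101	6.0
0110	7.5
0111	7.0
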