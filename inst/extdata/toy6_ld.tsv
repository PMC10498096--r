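s1	s2	s3	s4	s5	s6
1	0.8	0.5	0	0	0
0.8	1	0.9	0	0	0
0.5	0.9	1	0	0	0
0	0	0	1	0.2	0.1
0	0	0	0.2	1	0.6
0	0	0	0.1	0.6	1
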