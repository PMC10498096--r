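variant_id	chrom	pos_bp	effect_allele	other_allele	eaf	beta	se	pvalue
s1	1	100000	A	G	0.30	0.0703	0.01	1e-12
s2	1	150000	C	T	0.25	0.0611	0.01	1e-9
s3	1	190000	A	C	0.35	-0.0647	0.01	1e-10
s4	1	400000	G	T	0.40	0.0671	0.01	1e-11
s5	1	450000	A	G	0.20	-0.0549	0.01	4e-8
s6	1	460000	C	G	0.30	0.0794	0.01	1e-15
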