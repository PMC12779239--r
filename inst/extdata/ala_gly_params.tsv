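chain	residue_index	atom_name	mass	charge	sigma	epsilon
A	1	N	14.007	-0.40	0.325	0.71
A	1	CA	12.011	0.03	0.340	0.46
A	1	C	12.011	0.60	0.340	0.36
A	1	O	15.999	-0.55	0.296	0.88
A	1	CB	12.011	-0.18	0.340	0.46
A	2	N	14.007	-0.40	0.325	0.71
A	2	CA	12.011	0.02	0.340	0.46
A	2	C	12.011	0.52	0.340	0.36
A	2	O	15.999	-0.60	0.296	0.88
A	2	OXT	15.999	-0.62	0.296	0.88
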