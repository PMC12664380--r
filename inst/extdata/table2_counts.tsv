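hypothesis	category	all_genes	cluster10	cluster3
H1	HLH	187	50	1
H1	HLM	246	36	14
H1	HMH	632	159	9
H1	MLH	541	160	9
H1	MLM	3370	645	118
H2	LHH	0	0	0
H2	LHL	532	19	71
H2	LHM	43	7	2
H2	LMH	3	0	0
H2	LML	8482	582	941
H2	LMM	1051	132	50
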