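category	count
HHH	3418
HHL	37
HHM	669
HLH	187
HLL	98
HLM	246
HMH	632
HML	90
HMM	677
LHH	0
LHL	532
LHM	43
LLH	25
LLL	4549
LLM	730
LMH	3
LML	8482
LMM	1051
MHH	1100
MHL	456
MHM	929
MLH	541
MLL	2825
MLM	3370
MMH	1366
MML	4969
MMM	11676
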