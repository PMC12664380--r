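gene_set	total_pairs
all_genes	48701
cluster10	5223
cluster3	4015
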