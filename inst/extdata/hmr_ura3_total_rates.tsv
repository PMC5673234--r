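genotype	total_rate	n_mutations
wild type	6e-07	50
msh2	5e-06	50
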