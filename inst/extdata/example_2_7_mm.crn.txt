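# species (7)
dna_X	dna_X
P	none_P
dna_X:P	complex_dna_X_none_P
rna_X	rna_X
R	none_R
rna_X:R	complex_rna_X_none_R
protein_X	protein_X
# reactions (6)
dna_X + P --100--> dna_X:P
dna_X:P --10--> dna_X + P
dna_X:P --0.1--> dna_X + P + rna_X
rna_X + R --100--> rna_X:R
rna_X:R --10--> rna_X + R
rna_X:R --0.5--> rna_X + R + protein_X
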