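# species (3)
dna_X	dna_X
rna_X	rna_X
protein_X	protein_X
# reactions (2)
dna_X --0.1--> dna_X + rna_X
rna_X --0.5--> rna_X + protein_X
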