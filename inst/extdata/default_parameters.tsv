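# Ball-park global defaults for the shipped circuit specs.
mechanism	part_id	param_name	value
		kb	100
		ku	10
		ktx	0.1
		ktl	0.5
		K	20
		n	2
		kdil	0.01
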