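# Bistable toggle switch: two DNA assemblies mutually repress each other
# through negative Hill transcription.
mixture:
  name: toggle
  kind: expression_simple
components:
  - type: dna_assembly
    name: A
    promoter: prom
    rbs: rbs
    protein: A
    regulator: B
    mechanisms:
      transcription: hill_transcription_negative
  - type: dna_assembly
    name: B
    promoter: prom
    rbs: rbs
    protein: B
    regulator: A
    mechanisms:
      transcription: hill_transcription_negative
parameters:
  files:
    - default_parameters.tsv
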