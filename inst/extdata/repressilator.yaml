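# Three-gene repression ring (A represses B, B represses C, C represses A).
mixture:
  name: repressilator
  kind: expression_simple
components:
  - type: dna_assembly
    name: A
    promoter: prom
    rbs: rbs
    protein: A
    regulator: C
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
  - type: dna_assembly
    name: C
    promoter: prom
    rbs: rbs
    protein: C
    regulator: B
    mechanisms:
      transcription: hill_transcription_negative
parameters:
  files:
    - default_parameters.tsv
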