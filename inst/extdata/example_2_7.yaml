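# Single-gene expression example: one DNA assembly X (promoter + RBS + CDS)
# compiled with the simplest catalytic transcription/translation schemas.
mixture:
  name: mixture
  kind: custom
mechanisms:
  - simple_transcription
  - simple_translation
components:
  - type: dna_assembly
    name: X
    promoter: prom
    rbs: rbs
    protein: X
parameters:
  inline:
    kb: 100
    ku: 10
    ktx: 0.1
    ktl: 0.5
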