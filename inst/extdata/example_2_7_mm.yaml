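# The same DNA assembly X compiled under Michaelis-Menten transcription and
# translation (explicit polymerase P and ribosome R): only the mechanism
# selection changes, the component does not.
mixture:
  name: mixture
  kind: custom
mechanisms:
  - mm_transcription
  - mm_translation
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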