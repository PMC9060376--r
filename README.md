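# crnforge

`crnforge` is a compiler for chemical reaction networks (CRNs). It is
written for systems and synthetic biologists who design models the way they
design circuits — from reusable parts — rather than by writing out species
and reactions by hand. A model is specified as:

- **Components**: biomolecular parts or motifs (DNA assemblies with a
  promoter/RBS/CDS, enzymes, chemical complexes, annotated DNA constructs),
- **Mechanisms**: reaction schemas — functions *f* : (*S*′, *θ*) → (*S*, *R*)
  that turn input species plus rate parameters into generated species and
  reactions (simple catalytic transcription, Michaelis–Menten transcription
  with explicit polymerase, Hill-regulated transcription, multi-occupancy
  transcription, translation, binding, catalysis, RNA degradation), and
- **Mixtures**: contexts bundling components, a mechanism map, global
  mechanisms (dilution, RNA degradation) and a parameter database.

Compilation turns a mixture into an explicit CRN — a species set *S* and
reactions *I* → *O* with propensities *ρ*(*s*; *θ*) (mass action, Hill, or
general expressions) — and exports it as SBML Level 3 Version 1 for any
standard simulator. The point of the abstraction is that the *same* part
compiled under different schemas or contexts yields different networks
without rewriting the model: swap "simple transcription" for
"Michaelis–Menten transcription" and every affected reaction updates
automatically.

Two further pieces make large models practical:

- a **hierarchical parameter database** keyed by
  `(mechanism, part_id, name)` that defaults from most-specific to
  least-specific key in six tiers, so a handful of ball-park constants can
  drive a full compilation and be refined later (every resolution is
  logged and auditable), and
- **component enumeration**: enumerators *g* : *C* → *C*′ (with
  *C* ⊆ *C*′) generate new components during compilation, iterated to a
  fixed point or a depth cap — this is how a single annotated plasmid
  expands into its transcripts and proteins.

## A worked example

One gene `X` with a promoter, an RBS and a coding sequence, four ball-park
parameters, and the simplest transcription/translation schemas:

```r
library(crnforge)

G <- dna_assembly("X", promoter = "prom", rbs = "rbs", protein = "X")
M <- crn_mixture("mixture",
                 components = list(G),
                 mechanisms = list(mech_simple_transcription(),
                                   mech_simple_translation()),
                 parameters = c(kb = 100, ku = 10, ktx = 0.1, ktl = 0.5))
compile_crn(M)
#> Chemical reaction network: 3 species, 2 reactions
#> # species (3)
#> dna_X    dna_X
#> rna_X    rna_X
#> protein_X    protein_X
#> # reactions (2)
#> dna_X --0.1--> dna_X + rna_X
#> rna_X --0.5--> rna_X + protein_X
```

The gene transcribes at 0.1/time and the transcript translates at 0.5/time;
`kb` and `ku` are present but unused — no schema in this mixture binds
anything. Now swap only the two mechanisms for their Michaelis–Menten
versions (explicit polymerase `P` and ribosome `R`) and recompile the same
component; `tidy()` returns the network as a tibble:

```r
M2 <- crn_mixture("mixture",
                  components = list(G),
                  mechanisms = list(mech_mm_transcription(crn_species("P")),
                                    mech_mm_translation(crn_species("R"))),
                  parameters = c(kb = 100, ku = 10, ktx = 0.1, ktl = 0.5))
tidy(compile_crn(M2))
#> # A tibble: 6 × 5
#>   reaction inputs    outputs               propensity  rate
#>   <chr>    <chr>     <chr>                 <chr>      <dbl>
#> 1 r1       dna_X + P dna_X:P               massaction 100
#> 2 r2       dna_X:P   dna_X + P             massaction  10
#> 3 r3       dna_X:P   dna_X + P + rna_X     massaction   0.1
#> 4 r4       rna_X + R rna_X:R               massaction 100
#> 5 r5       rna_X:R   rna_X + R             massaction  10
#> 6 r6       rna_X:R   rna_X + R + protein_X massaction   0.5
```

Now `kb`/`ku` parameterize polymerase and ribosome binding (100) and
unbinding (10), and `dna_X:P` denotes the polymerase-bound promoter (`:`
marks bound-together species). `export_sbml(crn, path = "model.xml")`
writes either network as SBML. `make_example_2_7()` rebuilds this fixture;
`make_circuit()` builds a repression cascade, the toggle switch and the
repressilator; `params_audit(crn)` shows which database key supplied every
rate constant.

Declarative model specs (YAML) and a command line are included:

```sh
Rscript inst/scripts/crnforge.R compile inst/extdata/toggle_switch.yaml
Rscript inst/scripts/crnforge.R params-audit inst/extdata/toggle_switch.yaml
```

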