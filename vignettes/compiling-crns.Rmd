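---
title: "Compiling chemical reaction networks from parts, schemas and contexts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling chemical reaction networks from parts, schemas and contexts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnforge)
```

## The model

A chemical reaction network is a species set $S = \{S_i\}$ together with
reactions $I \xrightarrow{\rho(s;\theta)} O$, where $I$ and $O$ are
multisets of species, $s$ the vector of concentrations and $\theta$ rate
parameters. `crnforge` does not simulate these networks — it *compiles*
them from three kinds of objects and writes the result as SBML for
whatever simulator you prefer:

* **Mechanisms** are reaction schemas: pure functions
  $f : (S', \theta) \to (S, R)$ from input species and parameters to
  generated species ($S \supseteq S'$) and reactions. One biological
  process admits many schemas. Transcription ships in four resolutions —
  a single catalytic reaction; Michaelis–Menten binding of an explicit
  polymerase; a quasi-equilibrium Hill form for regulated promoters; and a
  multi-occupancy ladder allowing several polymerases per template.
* **Components** are parts: DNA assemblies, enzymes, chemical complexes,
  annotated DNA constructs. A component is not a species — it may emit
  none or many — and expresses its function by *calling* mechanism types
  ("transcription", "binding", ...) during compilation.
* **Mixtures** are contexts: a component list, a mechanism map, global
  mechanisms, and a parameter database. Components that carry their own
  mechanisms/parameters behave context-independently; all others inherit
  from the mixture, so one part can be dropped into different chemical
  environments and modeling resolutions unchanged.

Compilation runs seven ordered steps: global component enumeration, local
component enumeration, component updates (with mechanism resolution
local-before-mixture, then parameter resolution component-database-before-
mixture-database), one non-recursive pass of global mechanisms over every
species produced so far, and final assembly into a deduplicated,
deterministically ordered network. Compilation never mutates the mixture;
recompiling reproduces the identical serialized network, byte for byte.

## Parameters and the defaulting hierarchy

Rates resolve through keys `(mechanism, part_id, name)` where either of the
first two fields may be unspecified. The search order is

1. `(mechanism instance, part, name)`
2. `(mechanism type, part, name)`
3. `(—, part, name)`
4. `(mechanism instance, —, name)`
5. `(mechanism type, —, name)`
6. `(—, —, name)`

Part-specific entries beat mechanism-specific entries, which beat global
defaults: a part is the scientist's unit of refinement (a measured
promoter strength should override a generic transcription rate), whereas a
mechanism-level entry encodes "all reactions of this kind". The hierarchy
keeps both tiers for the mechanism *instance* and the mechanism *type*
because a user may parameterize one specific schema instance differently
from the type at large. When a component offers sub-part names (promoter,
RBS), they are tried as secondary `part_id` candidates, but only after the
component's own name misses within the part tiers. Every lookup is logged
with the key that matched and the tier it matched at (`params_audit()`),
which is how ball-park defaults are audited before refinement.

Parameter names follow the field's conventions: `kb`/`ku` for
binding/unbinding (1/(concentration·time), 1/time), `ktx`, `ktl`, `kcat`,
`kdeg`, `kdil` for catalytic steps (1/time), `K` (concentration) and `n`
(dimensionless) for Hill forms, and the optional `ktx_leak` (default 0)
for leaky repressed promoters. Initial concentrations are deliberately not
part of the CRN: they are read from `initial_concentration` entries keyed
by species canonical name (default 0) and written only to SBML.

## Species identity and naming

Everything downstream — deduplication, determinism, SBML ids — rests on
species identity, so canonical names must be injective. A simple species
renders as `material_name_attributes` (`dna_X`,
`protein_GFP_degradable`); a complex joins its members under a `complex_`
prefix (`complex_dna_X_none_P`, displayed `dna_X:P`). Flat concatenation
alone cannot distinguish `((A,B),C,D)` from `((A,B,C),D)`, nor an
attribute on a complex from one on its last member, so the grammar adds
two guards: complexes embedded *as members* carry an arity marker
(`complex2_`), and a complex's own attributes render directly after its
prefix. Names and attribute tags may not contain whitespace or `_` and may
not equal a reserved grammar token (the material names, `complex`,
`complex<digits>`, `small`, `molecule`). Under those rules the grammar
parses unambiguously, and an injectivity property test over random
species/complex trees backs this up. Nested complexes are preserved rather
than flattened — binding order is information that enumeration code may
rely on.

## Numerical and structural choices

* Mass-action propensities use the deterministic concentration convention
  ($s^2$ for a doubled input, not $s(s-1)$), matching ODE semantics.
* Reversible processes are stored as two irreversible reactions and SBML
  sets `reversible="false"` throughout — one uniform propensity path.
* Zero-rate reactions are retained: pruning would make the compiled
  *structure* depend on parameter values.
* `dna == transcript` (and `rna == protein`) are rejected by the
  expression schemas — they would create autocatalysis silently.
* Multi-occupancy transcription needs rates the cartoon does not fix: with
  $i$ polymerases bound, unbinding and production scale as $i\,k_u$ and
  $i\,k_{tx}$ (independent, exchangeable polymerases) while binding stays
  at $k_b$ up to the cap $m$. This is the simplest exchangeable model
  consistent with the picture; with $m = 1$ it reduces
  reaction-for-reaction to Michaelis–Menten transcription, which the test
  suite asserts.
* Homo-multimers bind in a single step ($nA \rightleftharpoons A_n$);
  sequential assembly would need an ordered mechanism nothing here
  specifies.
* Component iteration order is declaration order, and species/reaction
  order is first-encountered — chosen over sorting so that model text
  reads in the order it was written and determinism is trivial to state.

## Component enumeration

Enumerators $g : C \to C'$ with $C \subseteq C'$ run to a fixed point
under name identity — two generated components with equal names are the
same component, which is what prevents infinite renaming loops. The depth
cap defaults to 8 rounds; hitting it warns rather than errors, because a
truncated model is often still useful while prototyping. The compiler runs
global enumerators to their fixed point first, then local ones.

Transcript inference from an annotated construct scans from each promoter
in its orientation, collecting in-orientation RBS/CDS parts until the
first in-orientation terminator. Terminators are absolute (no leaky
termination). Decisions the scan semantics leaves open were resolved
permissively and are flagged in logs: a promoter with no terminator
produces a run-off transcript to the construct end (linear) or one full
revolution (circular), and circular scans wrap at most once so no
transcript is infinite. Each inferred transcript becomes an RNA-construct
component translating one protein per adjacent (RBS, CDS) pair in
transcript order. A brute-force oracle — every promoter against every
downstream terminator candidate, both strands — agrees with the scanner on
500 seeded random constructs of up to 12 parts in the test suite and in
`scripts/acceptance.R`.

## Global mechanisms

Dilution and RNA degradation act per species, not per part, so they live
on the mixture and are applied exactly once to every compiled species
passing a material/attribute filter. They are never applied to species
they themselves created (non-recursion): an mRNA–RNase complex created by
the degradation pass is not itself degraded. Machinery species (polymerase
`P`, ribosome `R`, `RNase`) in the `txtl_machinery` library mixture carry
a `"machinery"` attribute, and attribute deny-filters are the mechanism by
which they are exempted from dilution — the exemption is an explicit,
auditable tag rather than a hidden special case.

## SBML

Export targets SBML Level 3 Version 1 core, no packages: Hill and general
rates are written as explicit MathML formulas rather than any extension
construct, which maximizes simulator compatibility. The package carries
its own SBML layer on `xml2`: a deterministic writer, a reader, and a
structural consistency checker (SId grammar and uniqueness, dangling
species/compartment references, required attributes, every `<ci>` symbol
resolving to a declared id). Species elements and reactions carry
structured annotations in a package namespace recording the species
structure and the propensity payload; standard tools ignore them, while
the reader uses them to make export → import → re-export byte-identical.
Identifiers pass through `sanitize_id()`, an injective map onto the SId
grammar.

## What the fixtures do and do not show

The shipped fixtures are synthetic by construction: the single-gene
expression example (compiled under simple and Michaelis–Menten schemas),
the repression cascade, toggle switch and repressilator (idealized
contexts, default parameters `kb = 100, ku = 10, ktx = 0.1, ktl = 0.5,
K = 20, n = 2, kdil = 0.01` — order-of-magnitude values for bacterial gene
expression, documented as fixture defaults, not measurements), and seeded
random DNA constructs of up to 12 parts for the enumeration suites
(500 constructs keep the whole property run under a minute on one CPU).
Passing tests therefore demonstrate that compilation is *correct and
deterministic* — that schemas, resolution order, enumeration and export do
what this document says. They do not validate any rate constant against an
organism, and the idealized circuit mixtures omit resource competition,
growth and spatial effects that real cellular contexts add.

## Known limitations

* No simulation: networks are compiled and exported, never integrated.
* No ordered-polymer species class; DNA constructs model part *lists*,
  which is enough for transcript enumeration but not for, e.g., integrase
  site bookkeeping. The enumeration framework accepts user-written global
  enumerators for such systems, but none ships.
* Parameters are plain numbers: no units checking, no distributions.
* The SBML reader consumes this package's own annotated documents; it is
  not a general SBML importer.
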