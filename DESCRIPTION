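Package: crnforge
Title: Compile Chemical Reaction Networks from Biomolecular Parts and Contexts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compiler for chemical reaction networks (CRNs) in systems and
    synthetic biology. High-level model specifications -- biomolecular parts
    (components such as DNA assemblies, enzymes and chemical complexes),
    process models (mechanisms, i.e. reaction schemas for transcription,
    translation, binding, catalysis and degradation) and contexts (mixtures
    bundling components, mechanisms and parameters) -- are compiled into
    explicit species and reactions. The same part compiled under different
    schemas or contexts yields different networks without rewriting the model.
    Includes a hierarchical parameter database with defaulting search,
    combinatorial component enumeration (including transcript inference from
    annotated DNA constructs), genetic-circuit constructors (repression
    cascade, toggle switch, repressilator), SBML Level 3 Version 1 export,
    a declarative YAML model-specification reader and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    generics,
    stats,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
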