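#' Default circuit parameters
#'
#' The single global-default parameter set used by the shipped circuit
#' constructors: binding/unbinding `kb = 100`, `ku = 10` (1/(conc time),
#' 1/time), transcription `ktx = 0.1` and translation `ktl = 0.5` (1/time),
#' Hill half-max `K = 20` (conc) with coefficient `n = 2`, and dilution
#' `kdil = 0.01` (1/time). These are order-of-magnitude "ball-park" values
#' for bacterial gene expression, meant to be refined through the parameter
#' database, not measurements.
#'
#' @return Named numeric vector.
#' @export
default_circuit_parameters <- function() {
  c(kb = 100, ku = 10, ktx = 0.1, ktl = 0.5, K = 20, n = 2, kdil = 0.01)
}

#' The worked single-gene expression example
#'
#' One DNA assembly `X` carrying a promoter, an RBS and the coding sequence
#' for protein `X`, with the four-parameter set `kb = 100`, `ku = 10`,
#' `ktx = 0.1`, `ktl = 0.5`, placed in a mixture with one transcription and
#' one translation mechanism. Under `schema = "simple"` it compiles to the
#' two-reaction catalytic network
#' `dna_X -> dna_X + rna_X` (0.1), `rna_X -> rna_X + protein_X` (0.5);
#' under `schema = "mm"` to the six-reaction Michaelis–Menten network with
#' explicit polymerase `P` and ribosome `R`.
#'
#' @param schema `"simple"` or `"mm"`.
#' @return A `crn_mixture`.
#' @examples
#' compile_crn(make_example_2_7("simple"))
#' @export
make_example_2_7 <- function(schema = c("simple", "mm")) {
  schema <- match.arg(schema)
  G <- dna_assembly("X", promoter = "prom", rbs = "rbs", protein = "X")
  mechs <- if (schema == "simple") {
    list(mech_simple_transcription(), mech_simple_translation())
  } else {
    list(mech_mm_transcription(crn_species("P")),
         mech_mm_translation(crn_species("R")))
  }
  crn_mixture("mixture", components = list(G), mechanisms = mechs,
              parameters = c(kb = 100, ku = 10, ktx = 0.1, ktl = 0.5))
}

#' Genetic-circuit constructors
#'
#' Three classic transcription-factor circuits wired from DNA assemblies in
#' an idealized (simple transcription/translation, no machinery) context
#' with the [default_circuit_parameters()]:
#' \describe{
#'   \item{`repression`}{a constitutively expressed repressor represses a
#'     reporter. The repressor transcribes through the mixture's simple
#'     transcription mechanism; the reporter stores its own negative-Hill
#'     transcription mechanism locally — the same process, transcription,
#'     modeled two ways inside one model.}
#'   \item{`toggle`}{two assemblies `A` and `B` mutually repress each other
#'     through negative Hill transcription (the bistable toggle switch).}
#'   \item{`repressilator`}{three assemblies in a repression ring: A
#'     represses B, B represses C, C represses A (the three-gene
#'     oscillator).}
#' }
#'
#' @param kind `"repression"`, `"toggle"` or `"repressilator"`.
#' @return A `crn_mixture`.
#' @examples
#' glance(compile_crn(make_circuit("toggle")))
#' @export
make_circuit <- function(kind = c("repression", "toggle", "repressilator")) {
  kind <- match.arg(kind)
  params <- default_circuit_parameters()
  simple_mechs <- list(mech_simple_transcription(), mech_simple_translation())
  comps <- switch(
    kind,
    repression = list(
      dna_assembly("repressor", promoter = "prom", rbs = "rbs",
                   protein = "repressor"),
      dna_assembly("reporter", promoter = "prom", rbs = "rbs",
                   protein = "reporter", regulator = "repressor",
                   mechanisms = list(
                     transcription = mech_hill_transcription("negative")))
    ),
    toggle = list(
      dna_assembly("A", promoter = "prom", rbs = "rbs", protein = "A",
                   regulator = "B",
                   mechanisms = list(
                     transcription = mech_hill_transcription("negative"))),
      dna_assembly("B", promoter = "prom", rbs = "rbs", protein = "B",
                   regulator = "A",
                   mechanisms = list(
                     transcription = mech_hill_transcription("negative")))
    ),
    repressilator = {
      genes <- c("A", "B", "C")
      repressed_by <- c(A = "C", B = "A", C = "B")
      lapply(genes, function(g) {
        dna_assembly(g, promoter = "prom", rbs = "rbs", protein = g,
                     regulator = repressed_by[[g]],
                     mechanisms = list(
                       transcription = mech_hill_transcription("negative")))
      })
    })
  crn_mixture(kind, components = comps, mechanisms = simple_mechs,
              parameters = params)
}

#' Generate a random annotated DNA construct
#'
#' Seeded uniform draw of part types and orientations, used to stress
#' transcript enumeration against a brute-force oracle. The session RNG
#' state is restored on exit, so fixture generation never perturbs other
#' randomness.
#'
#' @param seed Integer seed; the same seed and knobs always give the same
#'   construct.
#' @param n_parts Number of parts (>= 1).
#' @param weights Named sampling weights over part types (default uniform
#'   over promoter/rbs/cds/terminator).
#' @param circular_prob Probability of circular topology (default 0.5).
#' @param name Construct name.
#' @return A `crn_dna_construct`.
#' @examples
#' random_construct(1, n_parts = 6)
#' @export
random_construct <- function(seed, n_parts = 6L,
                             weights = c(promoter = 1, rbs = 1, cds = 1,
                                         terminator = 1),
                             circular_prob = 0.5, name = "construct") {
  if (!is.numeric(n_parts) || n_parts < 1L) {
    stop("construct length must be >= 1", call. = FALSE)
  }
  bad <- setdiff(names(weights), PART_TYPES)
  if (length(bad)) {
    stop("unknown part types in weights: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed))
  types <- sample(names(weights), size = n_parts, replace = TRUE,
                  prob = as.numeric(weights))
  parts <- tibble::tibble(
    name = paste0(substr(types, 1L, 1L), seq_len(n_parts)),
    part_type = types,
    orientation = sample(c("forward", "reverse"), n_parts, replace = TRUE)
  )
  topology <- if (stats::runif(1) < circular_prob) "circular" else "linear"
  dna_construct(name, parts, topology = topology)
}
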