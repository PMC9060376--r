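#' Mechanisms: reaction schemas
#'
#' A mechanism is a pure function from input species plus rate parameters to
#' generated species and reactions — one biological process, many possible
#' model resolutions. Swapping the transcription mechanism from "simple"
#' (one catalytic production reaction) to "Michaelis–Menten" (explicit RNA
#' polymerase binding) changes the compiled network without touching the
#' component that requested transcription.
#'
#' A mechanism object carries an instance `name`, a `mechanism_type`
#' (`"transcription"`, `"translation"`, `"binding"`, `"catalysis"`,
#' `"rna_degradation"`, `"dilution"`), the parameter names it needs (these
#' are resolved through the parameter database), optional parameters with
#' defaults, any machinery species it references (polymerase, ribosome,
#' RNase), and an `update` function returning `list(species, reactions)`
#' where every reaction participant is included in `species`.
#'
#' @param name Instance name (used as the `mechanism` key tier in parameter
#'   lookups).
#' @param mechanism_type Process type string.
#' @param param_names Required parameter names.
#' @param optional_params Named numeric vector of optional parameters and
#'   their defaults.
#' @param machinery Named list of machinery `crn_species`.
#' @param update `function(mech, roles, params)` with `roles` a named list of
#'   species and `params` a named numeric vector.
#' @return A `crn_mechanism` object.
#' @export
crn_mechanism <- function(name, mechanism_type, param_names,
                          optional_params = numeric(), machinery = list(),
                          update) {
  stopifnot(is.character(name), is.character(mechanism_type),
            is.function(update))
  for (m in machinery) stopifnot(inherits(m, "crn_species"))
  structure(
    list(name = name, mechanism_type = mechanism_type,
         param_names = param_names, optional_params = optional_params,
         machinery = machinery, update = update),
    class = "crn_mechanism"
  )
}

#' @export
print.crn_mechanism <- function(x, ...) {
  cat("Mechanism ", x$name, " (type ", x$mechanism_type, "; parameters ",
      paste(x$param_names, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

mech_out <- function(species, reactions) {
  # close species over reaction participants, first-encountered order
  crn <- assemble_crn(species, reactions, warn = FALSE)
  list(species = crn$species, reactions = crn$reactions)
}

check_distinct <- function(a, b, what) {
  if (species_equal(a, b)) {
    stop(what, ": species ", sQuote(species_display(a)),
         " appears on both sides; this would silently create autocatalysis",
         call. = FALSE)
  }
}

# ---- transcription / translation schemas ----------------------------------

#' Simple (catalytic) transcription and translation
#'
#' The coarsest expression schemas: a single catalytic production reaction
#' with no machinery, `dna -> dna + transcript` at rate `ktx` and
#' `rna -> rna + protein` at rate `ktl`. Zero rates are retained. Producing a
#' species from itself (`dna == transcript`) is rejected.
#'
#' @param dna,transcript,rna,protein `crn_species`.
#' @param ktx,ktl Mass-action rate constants.
#' @return `list(species, reactions)`.
#' @examples
#' simple_transcription_update(crn_species("X", "dna"),
#'                             crn_species("X", "rna"), 0.1)
#' @export
simple_transcription_update <- function(dna, transcript, ktx) {
  check_distinct(dna, transcript, "simple transcription")
  check_rate(ktx, "ktx")
  mech_out(list(dna, transcript),
           list(crn_reaction(list(dna), list(dna, transcript),
                             massaction(ktx))))
}

#' @rdname simple_transcription_update
#' @export
simple_translation_update <- function(rna, protein, ktl) {
  check_distinct(rna, protein, "simple translation")
  check_rate(ktl, "ktl")
  mech_out(list(rna, protein),
           list(crn_reaction(list(rna), list(rna, protein),
                             massaction(ktl))))
}

#' Michaelis–Menten transcription and translation
#'
#' Explicit-machinery schemas: the polymerase (or ribosome) reversibly binds
#' the template and the bound complex catalytically releases machinery,
#' template and product:
#' `dna + P <-> dna:P` (rates `kb`/`ku`) and `dna:P -> dna + P + transcript`
#' (rate `ktx`). Three irreversible reactions and two new species (the bound
#' complex and the product) per call. The machinery cycle conserves P/R.
#'
#' @param dna,transcript,rna,protein `crn_species`.
#' @param rnap,ribosome The machinery species (polymerase P, ribosome R).
#' @param kb,ku,ktx,ktl Binding, unbinding and catalytic rate constants.
#' @return `list(species, reactions)`.
#' @export
mm_transcription_update <- function(dna, transcript, rnap, kb, ku, ktx) {
  check_distinct(dna, transcript, "transcription")
  check_rate(kb, "kb"); check_rate(ku, "ku"); check_rate(ktx, "ktx")
  bound <- crn_complex(list(dna, rnap))
  mech_out(
    list(dna, rnap, bound, transcript),
    c(reversible_pair(list(dna, rnap), list(bound), kb, ku),
      list(crn_reaction(list(bound), list(dna, rnap, transcript),
                        massaction(ktx))))
  )
}

#' @rdname mm_transcription_update
#' @export
mm_translation_update <- function(rna, protein, ribosome, kb, ku, ktl) {
  check_distinct(rna, protein, "translation")
  check_rate(kb, "kb"); check_rate(ku, "ku"); check_rate(ktl, "ktl")
  bound <- crn_complex(list(rna, ribosome))
  mech_out(
    list(rna, ribosome, bound, protein),
    c(reversible_pair(list(rna, ribosome), list(bound), kb, ku),
      list(crn_reaction(list(bound), list(rna, ribosome, protein),
                        massaction(ktl))))
  )
}

#' Hill-regulated transcription
#'
#' Quasi-equilibrium reduction of regulated transcription: a single
#' production reaction `dna -> dna + transcript` whose propensity is a Hill
#' function in a regulator species, scaled by the template concentration
#' (`d = dna`). `mode = "negative"` models repression
#' (\eqn{k\,d\,K^n/(K^n + r^n)}), `mode = "positive"` activation. An optional
#' mass-action leak reaction is added when `leak > 0` (parameter name
#' `ktx_leak`, default 0).
#'
#' @param dna,transcript,regulator `crn_species`.
#' @param mode `"negative"` or `"positive"`.
#' @param ktx Maximal transcription rate constant.
#' @param K Hill half-max constant (> 0).
#' @param n Hill coefficient (> 0).
#' @param leak Leak rate constant (default 0 = no leak reaction).
#' @return `list(species, reactions)`.
#' @export
hill_transcription_update <- function(dna, transcript, regulator,
                                      mode = c("negative", "positive"),
                                      ktx, K, n, leak = 0) {
  mode <- match.arg(mode)
  check_distinct(dna, transcript, "transcription")
  check_rate(ktx, "ktx"); check_rate(K, "K", positive = TRUE)
  check_rate(n, "n", positive = TRUE); check_rate(leak, "leak")
  prop <- if (mode == "negative") {
    hill_negative(ktx, K, n, regulator, scaling = dna)
  } else {
    hill_positive(ktx, K, n, regulator, scaling = dna)
  }
  rx <- list(crn_reaction(list(dna), list(dna, transcript), prop))
  if (leak > 0) {
    rx <- c(rx, list(crn_reaction(list(dna), list(dna, transcript),
                                  massaction(leak))))
  }
  mech_out(list(dna, transcript, regulator), rx)
}

#' Multi-occupancy Michaelis–Menten transcription
#'
#' Allows up to `m` polymerases on one template. Occupancy states are
#' \eqn{G_i} = the template complexed with \eqn{i} polymerase copies
#' (\eqn{G_0} is the bare template). For each \eqn{i = 1..m}:
#' `G_{i-1} + P <-> G_i` at `kb` / `i*ku`, and `G_i -> G_{i-1} + P +
#' transcript` at `i*ktx` — unbinding and production scale with occupancy
#' because the bound polymerases act independently, while binding is
#' occupancy-independent up to the cap. Total: `3m` irreversible reactions
#' and `m + 1` new species (the `m` occupancy states plus the transcript).
#' With `m = 1` this is reaction-for-reaction identical to
#' [mm_transcription_update()].
#'
#' @param dna,transcript,rnap `crn_species`.
#' @param m Maximum occupancy (positive integer).
#' @param kb,ku,ktx Rate constants.
#' @return `list(species, reactions)`.
#' @export
multi_occupancy_transcription_update <- function(dna, transcript, rnap,
                                                 m, kb, ku, ktx) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    stop("max occupancy m must be a positive integer", call. = FALSE)
  }
  m <- as.integer(m)
  check_distinct(dna, transcript, "transcription")
  check_rate(kb, "kb"); check_rate(ku, "ku"); check_rate(ktx, "ktx")
  states <- vector("list", m + 1L)
  states[[1L]] <- dna
  for (i in seq_len(m)) {
    states[[i + 1L]] <- crn_complex(c(list(dna), rep(list(rnap), i)))
  }
  rx <- list()
  for (i in seq_len(m)) {
    rx <- c(rx,
            reversible_pair(list(states[[i]], rnap), list(states[[i + 1L]]),
                            kb, i * ku),
            list(crn_reaction(list(states[[i + 1L]]),
                              list(states[[i]], rnap, transcript),
                              massaction(i * ktx))))
  }
  mech_out(c(states, list(rnap, transcript)), rx)
}

# ---- catalysis / binding / degradation schemas ----------------------------

#' Michaelis–Menten catalysis
#'
#' `enzyme + substrate <-> enzyme:substrate` at `kb`/`ku`, then
#' `enzyme:substrate -> enzyme + product` at `kcat`. Substrate and product
#' must differ; enzyme equal to substrate is permitted (the template applies
#' verbatim, forming `E:E`).
#'
#' @param enzyme,substrate,product `crn_species`.
#' @param kb,ku,kcat Rate constants.
#' @return `list(species, reactions)`.
#' @export
mm_catalysis_update <- function(enzyme, substrate, product, kb, ku, kcat) {
  check_distinct(substrate, product, "catalysis")
  check_rate(kb, "kb"); check_rate(ku, "ku"); check_rate(kcat, "kcat")
  bound <- crn_complex(list(enzyme, substrate))
  mech_out(
    list(enzyme, substrate, bound, product),
    c(reversible_pair(list(enzyme, substrate), list(bound), kb, ku),
      list(crn_reaction(list(bound), list(enzyme, product),
                        massaction(kcat))))
  )
}

#' One-step binding
#'
#' All members bind in a single reversible step:
#' `A + B + ... <-> A:B:...` at `kb`/`ku`. Repeated members model
#' homo-multimers (`list(A, A)` gives the homodimer `A:A`).
#'
#' @param members List of at least two `crn_species`.
#' @param kb,ku Rate constants.
#' @return `list(species, reactions)`.
#' @export
one_step_binding_update <- function(members, kb, ku) {
  if (!is.list(members) || length(members) < 2L) {
    stop("binding needs at least 2 member species", call. = FALSE)
  }
  check_rate(kb, "kb"); check_rate(ku, "ku")
  bound <- crn_complex(members)
  mech_out(c(members, list(bound)),
           reversible_pair(members, list(bound), kb, ku))
}

#' Michaelis–Menten degradation
#'
#' A degradation machine (e.g. an RNase) reversibly binds its target and
#' consumes it: `target + rnase <-> target:rnase` at `kb`/`ku`, then
#' `target:rnase -> rnase` at `kdeg`. The machinery is conserved across the
#' cycle; the target is consumed.
#'
#' @param target,rnase `crn_species`.
#' @param kb,ku,kdeg Rate constants.
#' @return `list(species, reactions)`.
#' @export
mm_degradation_update <- function(target, rnase, kb, ku, kdeg) {
  check_rate(kb, "kb"); check_rate(ku, "ku"); check_rate(kdeg, "kdeg")
  bound <- crn_complex(list(target, rnase))
  mech_out(
    list(target, rnase, bound),
    c(reversible_pair(list(target, rnase), list(bound), kb, ku),
      list(crn_reaction(list(bound), list(rnase), massaction(kdeg))))
  )
}

# ---- mechanism objects -----------------------------------------------------

#' Built-in mechanism constructors
#'
#' These wrap the `*_update()` schema functions into [crn_mechanism] objects
#' that components resolve by `mechanism_type` during compilation. Machinery
#' species (polymerase `P`, ribosome `R`, RNase `RNase`) are carried by the
#' mechanism instance, mirroring how a context supplies its machinery.
#'
#' @param rnap,ribosome,rnase Machinery species (defaults: untyped `P`, `R`,
#'   `RNase`).
#' @param mode Hill regulation mode, `"negative"` or `"positive"`.
#' @param max_occupancy Occupancy cap for the multi-occupancy schema.
#' @return A `crn_mechanism`.
#' @name mechanism_library
NULL

#' @rdname mechanism_library
#' @export
mech_simple_transcription <- function() {
  crn_mechanism(
    "simple_transcription", "transcription", "ktx",
    update = function(mech, roles, params) {
      simple_transcription_update(roles$dna, roles$transcript,
                                  params[["ktx"]])
    })
}

#' @rdname mechanism_library
#' @export
mech_simple_translation <- function() {
  crn_mechanism(
    "simple_translation", "translation", "ktl",
    update = function(mech, roles, params) {
      simple_translation_update(roles$rna, roles$protein, params[["ktl"]])
    })
}

#' @rdname mechanism_library
#' @export
mech_mm_transcription <- function(rnap = crn_species("P")) {
  crn_mechanism(
    "mm_transcription", "transcription", c("kb", "ku", "ktx"),
    machinery = list(rnap = rnap),
    update = function(mech, roles, params) {
      mm_transcription_update(roles$dna, roles$transcript,
                              mech$machinery$rnap, params[["kb"]],
                              params[["ku"]], params[["ktx"]])
    })
}

#' @rdname mechanism_library
#' @export
mech_mm_translation <- function(ribosome = crn_species("R")) {
  crn_mechanism(
    "mm_translation", "translation", c("kb", "ku", "ktl"),
    machinery = list(ribosome = ribosome),
    update = function(mech, roles, params) {
      mm_translation_update(roles$rna, roles$protein,
                            mech$machinery$ribosome, params[["kb"]],
                            params[["ku"]], params[["ktl"]])
    })
}

#' @rdname mechanism_library
#' @export
mech_hill_transcription <- function(mode = c("negative", "positive")) {
  mode <- match.arg(mode)
  crn_mechanism(
    paste0("hill_", mode, "_transcription"), "transcription",
    c("ktx", "K", "n"), optional_params = c(ktx_leak = 0),
    update = function(mech, roles, params) {
      if (is.null(roles$regulator)) {
        stop("Hill transcription needs a regulator species; set the ",
             "component's 'regulator' field", call. = FALSE)
      }
      hill_transcription_update(roles$dna, roles$transcript, roles$regulator,
                                mode = mode, ktx = params[["ktx"]],
                                K = params[["K"]], n = params[["n"]],
                                leak = params[["ktx_leak"]])
    })
}

#' @rdname mechanism_library
#' @export
mech_multi_occupancy_transcription <- function(rnap = crn_species("P"),
                                               max_occupancy = 2) {
  crn_mechanism(
    "multi_occupancy_transcription", "transcription", c("kb", "ku", "ktx"),
    machinery = list(rnap = rnap),
    update = function(mech, roles, params) {
      multi_occupancy_transcription_update(
        roles$dna, roles$transcript, mech$machinery$rnap,
        m = max_occupancy, kb = params[["kb"]], ku = params[["ku"]],
        ktx = params[["ktx"]])
    })
}

#' @rdname mechanism_library
#' @export
mech_one_step_binding <- function() {
  crn_mechanism(
    "one_step_binding", "binding", c("kb", "ku"),
    update = function(mech, roles, params) {
      one_step_binding_update(roles$members, params[["kb"]], params[["ku"]])
    })
}

#' @rdname mechanism_library
#' @export
mech_mm_catalysis <- function() {
  crn_mechanism(
    "mm_catalysis", "catalysis", c("kb", "ku", "kcat"),
    update = function(mech, roles, params) {
      mm_catalysis_update(roles$enzyme, roles$substrate, roles$product,
                          params[["kb"]], params[["ku"]], params[["kcat"]])
    })
}

#' @rdname mechanism_library
#' @export
mech_mm_degradation <- function(rnase = crn_species("RNase")) {
  crn_mechanism(
    "mm_rna_degradation", "rna_degradation", c("kb", "ku", "kdeg"),
    machinery = list(rnase = rnase),
    update = function(mech, roles, params) {
      mm_degradation_update(roles$species, mech$machinery$rnase,
                            params[["kb"]], params[["ku"]],
                            params[["kdeg"]])
    })
}

#' @rdname mechanism_library
#' @export
mech_dilution <- function() {
  crn_mechanism(
    "dilution", "dilution", "kdil",
    update = function(mech, roles, params) {
      mech_out(list(roles$species),
               list(crn_reaction(list(roles$species), list(),
                                 massaction(params[["kdil"]]))))
    })
}

# ---- mechanism registry ----------------------------------------------------

.registries <- new.env(parent = emptyenv())
.registries$mechanisms <- list()
.registries$components <- list()

#' Mechanism registry
#'
#' Model-specification files select mechanisms by registered name. The
#' built-in library is registered at load time; user code can register
#' additional constructors (a function returning a [crn_mechanism]).
#'
#' @param name Registered name.
#' @param constructor Zero-argument function returning a `crn_mechanism`.
#' @return `register_mechanism` returns `name` invisibly;
#'   `registered_mechanisms` the sorted names; `get_mechanism` a constructed
#'   `crn_mechanism`.
#' @export
register_mechanism <- function(name, constructor) {
  stopifnot(is.character(name), is.function(constructor))
  .registries$mechanisms[[name]] <- constructor
  invisible(name)
}

#' @rdname register_mechanism
#' @export
registered_mechanisms <- function() sort_c(names(.registries$mechanisms))

#' @rdname register_mechanism
#' @export
get_mechanism <- function(name) {
  ctor <- .registries$mechanisms[[name]]
  if (is.null(ctor)) {
    stop("unknown mechanism ", sQuote(name), "; registered: ",
         paste(registered_mechanisms(), collapse = ", "), call. = FALSE)
  }
  ctor()
}

register_builtin_mechanisms <- function() {
  register_mechanism("simple_transcription", mech_simple_transcription)
  register_mechanism("simple_translation", mech_simple_translation)
  register_mechanism("mm_transcription", mech_mm_transcription)
  register_mechanism("mm_translation", mech_mm_translation)
  register_mechanism("hill_transcription_negative",
                     function() mech_hill_transcription("negative"))
  register_mechanism("hill_transcription_positive",
                     function() mech_hill_transcription("positive"))
  register_mechanism("multi_occupancy_transcription",
                     mech_multi_occupancy_transcription)
  register_mechanism("one_step_binding", mech_one_step_binding)
  register_mechanism("mm_catalysis", mech_mm_catalysis)
  register_mechanism("mm_rna_degradation", mech_mm_degradation)
  register_mechanism("dilution", mech_dilution)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_mechanisms()
  register_builtin_components()
}
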