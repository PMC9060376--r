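#' Mixtures: the compilation context
#'
#' A mixture bundles components, a mechanism map, global mechanisms, a
#' parameter database and enumerators into one chemical/modeling context.
#' Compiling the same component list under different mixtures yields
#' different networks — that context swap, with no change to the components
#' themselves, is the point of the abstraction.
#'
#' @param name Mixture name.
#' @param components List of [crn_component]s.
#' @param mechanisms The mixture's mechanism map: a list of
#'   [crn_mechanism]s, keyed by mechanism type (unnamed lists are keyed from
#'   each mechanism's `mechanism_type`).
#' @param global_mechanisms List of [global_mechanism]s.
#' @param parameters A [parameter_db], or a named numeric vector of global
#'   defaults.
#' @param global_enumerators List of global [component_enumerator]s.
#' @param max_enumeration_depth Recursion-depth cap for component
#'   enumeration (default 8; hitting the cap warns).
#' @return A `crn_mixture` object.
#' @export
crn_mixture <- function(name, components = list(), mechanisms = list(),
                        global_mechanisms = list(),
                        parameters = parameter_db(),
                        global_enumerators = list(),
                        max_enumeration_depth = 8L) {
  if (!inherits(parameters, "parameter_db")) {
    parameters <- parameter_db(parameters,
                               provenance = paste0("mixture:", name))
  }
  for (comp in components) stopifnot(inherits(comp, "crn_component"))
  mechanisms <- key_mechanisms(mechanisms)
  for (gm in global_mechanisms) {
    stopifnot(inherits(gm, "crn_global_mechanism"))
  }
  structure(
    list(name = name, components = components, mechanisms = mechanisms,
         global_mechanisms = global_mechanisms, parameters = parameters,
         global_enumerators = global_enumerators,
         max_enumeration_depth = as.integer(max_enumeration_depth)),
    class = "crn_mixture"
  )
}

key_mechanisms <- function(mechanisms) {
  if (length(mechanisms) == 0L) return(list())
  for (m in mechanisms) stopifnot(inherits(m, "crn_mechanism"))
  if (is.null(names(mechanisms)) || any(!nzchar(names(mechanisms)))) {
    names(mechanisms) <- vapply(mechanisms, `[[`, character(1),
                                "mechanism_type")
  }
  if (anyDuplicated(names(mechanisms))) {
    stop("mixture has more than one mechanism for type(s): ",
         paste(unique(names(mechanisms)[duplicated(names(mechanisms))]),
               collapse = ", "), call. = FALSE)
  }
  mechanisms
}

#' @export
print.crn_mixture <- function(x, ...) {
  cat("Mixture ", x$name, ": ", length(x$components), " components, ",
      length(x$mechanisms), " mechanisms (",
      paste(names(x$mechanisms), collapse = ", "), "), ",
      length(x$global_mechanisms), " global mechanisms, ",
      nrow(x$parameters), " parameters\n", sep = "")
  invisible(x)
}

#' Global mechanisms
#'
#' A global mechanism is stored on the mixture and applied exactly once to
#' every compiled species that passes its filter — dilution and RNA
#' degradation are the canonical examples. It is never applied to species it
#' (or another global mechanism) created: global mechanisms are not called
#' recursively.
#'
#' The filter selects species by material type and/or attribute tags:
#' `materials` is an allow-list of material types (`NULL` = any),
#' `with_attributes` requires every listed tag, `without_attributes` rejects
#' any listed tag (the usual way to exempt machinery species, via the
#' `"machinery"` tag).
#'
#' @param mechanism A [crn_mechanism] whose update takes a single species
#'   role named `species`.
#' @param materials Allowed material types or `NULL`.
#' @param with_attributes,without_attributes Attribute tag filters.
#' @return A `crn_global_mechanism`.
#' @export
global_mechanism <- function(mechanism, materials = NULL,
                             with_attributes = NULL,
                             without_attributes = NULL) {
  stopifnot(inherits(mechanism, "crn_mechanism"))
  structure(
    list(mechanism = mechanism, materials = materials,
         with_attributes = with_attributes,
         without_attributes = without_attributes),
    class = "crn_global_mechanism"
  )
}

gm_filter_pass <- function(gm, sp) {
  if (!is.null(gm$materials) && !(sp$material %in% gm$materials)) {
    return(FALSE)
  }
  if (!is.null(gm$with_attributes) &&
      !all(gm$with_attributes %in% sp$attributes)) {
    return(FALSE)
  }
  if (!is.null(gm$without_attributes) &&
      any(gm$without_attributes %in% sp$attributes)) {
    return(FALSE)
  }
  TRUE
}

#' Apply a mixture's global mechanisms to a species set
#'
#' Each species passing a global mechanism's filter gets that mechanism
#' applied once; species created here are not re-fed into any global
#' mechanism (non-recursion). Parameters are resolved from the mixture's
#' database with the species' canonical name (and bare name) as `part_id`
#' candidates.
#'
#' @param mixture A `crn_mixture`.
#' @param species List of species compiled so far.
#' @param ctx Optional compile context for audit logging.
#' @return `list(species, reactions, log)`; `log` records, per application,
#'   the species it was applied to and the canonical names it created.
#' @export
apply_global_mechanisms <- function(mixture, species, ctx = NULL) {
  if (is.null(ctx)) {
    ctx <- compile_context(mixture$mechanisms, mixture$parameters)
  }
  tab <- stoich_table(species)
  uniq <- attr(tab, "species")
  existing <- names(tab)
  new_species <- list(); reactions <- list(); log <- list()
  for (gm in mixture$global_mechanisms) {
    mech <- gm$mechanism
    for (sp in uniq) {
      if (!gm_filter_pass(gm, sp)) next
      pseudo <- list(name = canonical_name(sp), local_parameters = NULL)
      params <- vapply(mech$param_names, function(nm) {
        resolve_parameter(pseudo, mixture$parameters, mech, nm,
                          extra_part_ids = if (!is_complex(sp)) sp$name
                                           else character(),
                          ctx = ctx)
      }, numeric(1))
      names(params) <- mech$param_names
      for (nm in names(mech$optional_params)) {
        params[[nm] ] <- resolve_parameter(
          pseudo, mixture$parameters, mech, nm,
          default = mech$optional_params[[nm]], ctx = ctx)
      }
      upd <- mech$update(mech, list(species = sp), params)
      created <- setdiff(vapply(upd$species, canonical_name, character(1)),
                         existing)
      new_species <- c(new_species, upd$species)
      reactions <- c(reactions, upd$reactions)
      log[[length(log) + 1L]] <- list(
        mechanism = mech$name, applied_to = canonical_name(sp),
        created = created,
        inputs = unique(unlist(lapply(upd$reactions, function(r)
          vapply(r$inputs, canonical_name, character(1))))))
    }
  }
  list(species = new_species, reactions = reactions, log = log)
}

#' Compile a mixture into a chemical reaction network
#'
#' Runs the seven compilation steps in order: (1) global component
#' enumeration to a fixed point or the depth cap; (2) local component
#' enumeration likewise; (3) every component (original and enumerated)
#' generates its species and reactions, (4) resolving each mechanism
#' locally first and then from the mixture, and (5) resolving each
#' parameter against the component's database first and then the
#' mixture's; (6) global mechanisms are applied once, non-recursively, to
#' every species produced so far; (7) everything is assembled into a
#' deduplicated, deterministically ordered network. Compilation never
#' mutates the mixture, so recompiling reproduces the identical network.
#'
#' @param mixture A `crn_mixture`.
#' @param max_depth Override for the mixture's enumeration depth cap.
#' @return A `crn`. Attributes carry the audit trail: `params_audit` (one
#'   row per parameter lookup, see [params_audit()]), `mechanism_log`,
#'   `global_mechanism_log` and `initial` (initial concentrations resolved
#'   from `initial_concentration` parameter keys, default 0).
#' @examples
#' m <- crn_mixture(
#'   "mixture",
#'   components = list(dna_assembly("X", promoter = "prom", rbs = "rbs",
#'                                  protein = "X")),
#'   mechanisms = list(mech_simple_transcription(),
#'                     mech_simple_translation()),
#'   parameters = c(kb = 100, ku = 10, ktx = 0.1, ktl = 0.5))
#' compile_crn(m)
#' @export
compile_crn <- function(mixture, max_depth = mixture$max_enumeration_depth) {
  stopifnot(inherits(mixture, "crn_mixture"))
  # steps 1-2: global, then local, component enumeration
  comps <- enumerate_fixed_point(mixture$components,
                                 mixture$global_enumerators,
                                 max_depth = max_depth,
                                 include_local = FALSE)
  comps <- enumerate_fixed_point(comps, list(), max_depth = max_depth,
                                 include_local = TRUE)
  # steps 3-5: component updates with local-then-mixture resolution
  ctx <- compile_context(mixture$mechanisms, mixture$parameters)
  species <- list(); reactions <- list()
  for (comp in comps) {
    upd <- component_update(comp, ctx)
    species <- c(species, upd$species)
    reactions <- c(reactions, upd$reactions)
  }
  # step 6: global mechanisms, once per species, non-recursive
  gm <- apply_global_mechanisms(mixture, species, ctx = ctx)
  # step 7: assemble
  crn <- assemble_crn(c(species, gm$species), c(reactions, gm$reactions),
                      warn = FALSE)
  attr(crn, "params_audit") <- param_audit_table(ctx)
  attr(crn, "mechanism_log") <- ctx$log$mechanisms
  attr(crn, "global_mechanism_log") <- gm$log
  attr(crn, "initial") <- initial_concentrations(mixture, crn)
  crn
}

#' Initial concentrations for a compiled network
#'
#' Initial concentrations are not part of the CRN proper; they are read from
#' parameter entries named `initial_concentration` whose `part_id` is the
#' species canonical name (mechanism unspecified), defaulting to 0, and are
#' written to SBML at export.
#'
#' @param mixture The compiled `crn_mixture`.
#' @param crn The compiled `crn`.
#' @return Named numeric vector, one entry per species.
#' @export
initial_concentrations <- function(mixture, crn) {
  db <- mixture$parameters
  vals <- vapply(crn$species, function(sp) {
    key <- canonical_name(sp)
    hit <- which(is.na(db$mechanism) & !is.na(db$part_id) &
                   db$part_id == key & db$name == "initial_concentration")
    if (length(hit)) db$value[hit[[1L]]] else 0
  }, numeric(1))
  names(vals) <- species_names(crn)
  vals
}

#' Parameter-resolution audit of a compiled network
#'
#' One row per parameter lookup performed during compilation: the component
#' and mechanism that asked, the requested part ids, the key that matched,
#' which search tier it matched at, the value and its provenance. This is
#' how defaulted "ball-park" values are audited before refinement.
#'
#' @param crn A `crn` returned by [compile_crn()].
#' @return A tibble.
#' @export
params_audit <- function(crn) {
  a <- attr(crn, "params_audit")
  if (is.null(a)) {
    stop("this CRN carries no audit trail (not produced by compile_crn)",
         call. = FALSE)
  }
  a
}

#' Library mixtures
#'
#' Pre-assembled contexts at three levels of modeling complexity:
#' \describe{
#'   \item{`expression_simple`}{catalytic one-reaction transcription and
#'     translation; no machinery. Genes transcribe and transcripts translate
#'     catalytically.}
#'   \item{`expression_mm`}{Michaelis–Menten transcription and translation
#'     with explicit polymerase `P` and ribosome `R` machinery species.}
#'   \item{`txtl_machinery`}{as `expression_mm`, with `P`, `R` and `RNase`
#'     tagged with the `"machinery"` attribute (which exempts them from
#'     attribute-filtered global mechanisms such as dilution) plus RNA
#'     degradation by `RNase` as a global mechanism over all RNA species.}
#' }
#' All kinds also carry one-step binding and Michaelis–Menten catalysis
#' mechanisms so complexes and enzymes compile without further setup.
#'
#' @param kind One of `"expression_simple"`, `"expression_mm"`,
#'   `"txtl_machinery"`.
#' @param parameters A [parameter_db] or named numeric vector.
#' @param components List of components to place in the mixture.
#' @param name Mixture name (defaults to the kind).
#' @param max_enumeration_depth Enumeration depth cap.
#' @return A `crn_mixture`.
#' @export
make_library_mixture <- function(kind, parameters = parameter_db(),
                                 components = list(), name = kind,
                                 max_enumeration_depth = 8L) {
  kinds <- c("expression_simple", "expression_mm", "txtl_machinery")
  if (!is.character(kind) || length(kind) != 1L || !kind %in% kinds) {
    stop("unknown mixture kind ", sQuote(kind), "; available: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  }
  common <- list(mech_one_step_binding(), mech_mm_catalysis())
  if (kind == "expression_simple") {
    mechs <- c(list(mech_simple_transcription(), mech_simple_translation()),
               common)
    gms <- list()
  } else if (kind == "expression_mm") {
    mechs <- c(list(mech_mm_transcription(crn_species("P")),
                    mech_mm_translation(crn_species("R"))), common)
    gms <- list()
  } else {
    machinery <- "machinery"
    P <- crn_species("P", attributes = machinery)
    R <- crn_species("R", attributes = machinery)
    RNase <- crn_species("RNase", attributes = machinery)
    mechs <- c(list(mech_mm_transcription(P), mech_mm_translation(R)),
               common)
    gms <- list(global_mechanism(mech_mm_degradation(RNase),
                                 materials = "rna",
                                 without_attributes = machinery))
  }
  crn_mixture(name, components = components, mechanisms = mechs,
              global_mechanisms = gms, parameters = parameters,
              max_enumeration_depth = max_enumeration_depth)
}
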