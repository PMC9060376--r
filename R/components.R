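#' Components: biomolecular parts
#'
#' Components are biochemical parts or motifs — promoters bundled into DNA
#' assemblies, enzymes, chemical complexes. A component is not a species: it
#' expresses its functionality by calling mechanisms during compilation and
#' may emit zero, one or many species. Components can carry their own
#' mechanisms, parameters and enumerators (context-independent behavior) or
#' rely on the mixture to supply them (context-dependent behavior); local
#' always beats mixture.
#'
#' @param name Component name; used as the primary `part_id` in parameter
#'   lookups. Same constraints as species names.
#' @param type Component type string (for the registry / model specs).
#' @param mechanisms Named list of local [crn_mechanism]s, keyed by
#'   mechanism type.
#' @param parameters Local parameters: a [parameter_db], a named numeric
#'   vector, or `NULL`.
#' @param enumerators List of local [component_enumerator]s.
#' @param ... Type-specific fields stored on the component.
#' @return A `crn_component` object.
#' @export
crn_component <- function(name, type, mechanisms = list(), parameters = NULL,
                          enumerators = list(), ...) {
  check_token(name, "component name")
  if (!is.null(parameters) && !inherits(parameters, "parameter_db")) {
    parameters <- parameter_db(parameters, provenance = paste0("component:",
                                                               name))
  }
  if (length(mechanisms)) {
    stopifnot(!is.null(names(mechanisms)))
    for (m in mechanisms) stopifnot(inherits(m, "crn_mechanism"))
  }
  structure(
    c(list(name = name, type = type, local_mechanisms = mechanisms,
           local_parameters = parameters, local_enumerators = enumerators),
      list(...)),
    class = c(paste0("crn_", type), "crn_component")
  )
}

#' @export
print.crn_component <- function(x, ...) {
  cat("Component ", x$name, " (", x$type, ")\n", sep = "")
  invisible(x)
}

# ---- compile context -------------------------------------------------------

# The context a component updates against: the mixture's mechanism map and
# parameter database, plus an accumulator environment for resolution logs
# (mechanism resolutions and every parameter lookup, for params-audit).
compile_context <- function(mechanisms = list(), parameters = parameter_db()) {
  log_env <- new.env(parent = emptyenv())
  log_env$params <- list()
  log_env$mechanisms <- list()
  list(mechanisms = mechanisms, parameters = parameters, log = log_env)
}

log_param <- function(ctx, row) {
  ctx$log$params[[length(ctx$log$params) + 1L]] <- row
  invisible(NULL)
}

param_audit_table <- function(ctx) {
  rows <- ctx$log$params
  if (length(rows) == 0L) {
    return(tibble::tibble(component = character(), mechanism = character(),
                          mechanism_type = character(), parameter = character(),
                          requested_part = character(), matched_key = character(),
                          tier = integer(), value = numeric(),
                          source = character(), provenance = character()))
  }
  do.call(rbind, lapply(rows, function(r) tibble::as_tibble(r)))
}

# ---- resolution ------------------------------------------------------------

#' Resolve a mechanism for a component
#'
#' Mechanisms stored inside the component are used preferentially; if the
#' component has no mechanism of the requested type, it is retrieved from
#' the mixture's mechanism map. Every resolution is logged when a context is
#' supplied.
#'
#' @param component A `crn_component`.
#' @param mixture_mechanisms Named list of mechanisms keyed by type (the
#'   mixture's map).
#' @param mechanism_type The type to resolve (e.g. `"transcription"`).
#' @param ctx Optional compile context for logging.
#' @return A `crn_mechanism`; error naming the component and type if the
#'   type is absent from both maps.
#' @export
resolve_mechanism <- function(component, mixture_mechanisms, mechanism_type,
                              ctx = NULL) {
  mech <- component$local_mechanisms[[mechanism_type]]
  source <- "component"
  if (is.null(mech)) {
    mech <- mixture_mechanisms[[mechanism_type]]
    source <- "mixture"
  }
  if (is.null(mech)) {
    stop("component ", sQuote(component$name), " requires a mechanism of ",
         "type ", sQuote(mechanism_type),
         ", found neither locally nor in the mixture", call. = FALSE)
  }
  if (!is.null(ctx)) {
    ctx$log$mechanisms[[length(ctx$log$mechanisms) + 1L]] <-
      list(component = component$name, mechanism_type = mechanism_type,
           mechanism = mech$name, source = source)
  }
  mech
}

#' Resolve a parameter for a component
#'
#' Runs [find_parameter()] against the component's own database first (if it
#' has one) and falls back to the mixture's database. The component's name is
#' the primary `part_id`; sub-part names (promoter, RBS) may be supplied as
#' secondary part candidates tried only when the primary tiers miss. On a
#' miss in both databases the error lists both attempted key sequences.
#'
#' @param component A `crn_component`.
#' @param mixture_db The mixture's [parameter_db].
#' @param mech The calling [crn_mechanism] (its name and type key tiers 1–2
#'   and 4–5 of the search).
#' @param name Parameter name.
#' @param extra_part_ids Secondary part-id candidates.
#' @param default Optional default returned (and logged) when both databases
#'   miss; `NULL` (the default) makes a miss an error.
#' @param ctx Optional compile context for audit logging.
#' @return The numeric value.
#' @export
resolve_parameter <- function(component, mixture_db, mech, name,
                              extra_part_ids = character(), default = NULL,
                              ctx = NULL) {
  part_ids <- unique(c(component$name, extra_part_ids))
  try_db <- function(db) {
    find_parameter(db, mechanism_name = mech$name,
                   mechanism_type = mech$mechanism_type,
                   part_id = part_ids, name = name)
  }
  hit <- NULL; source <- NA_character_; errors <- character()
  if (!is.null(component$local_parameters)) {
    hit <- tryCatch(try_db(component$local_parameters), error = function(e) {
      errors <<- c(errors, paste0("component database: ",
                                  conditionMessage(e)))
      NULL
    })
    if (!is.null(hit)) source <- "component"
  }
  if (is.null(hit)) {
    hit <- tryCatch(try_db(mixture_db), error = function(e) {
      errors <<- c(errors, paste0("mixture database: ", conditionMessage(e)))
      NULL
    })
    if (!is.null(hit)) source <- "mixture"
  }
  if (is.null(hit)) {
    if (!is.null(default)) {
      hit <- list(value = default,
                  key = list(mechanism = NA_character_,
                             part_id = NA_character_, name = name),
                  tier = NA_integer_, provenance = "built-in default")
      source <- "default"
    } else {
      stop("parameter ", sQuote(name), " unresolved for component ",
           sQuote(component$name), ":\n  ",
           paste(errors, collapse = "\n  "), call. = FALSE)
    }
  }
  if (!is.null(ctx)) {
    log_param(ctx, list(
      component = component$name, mechanism = mech$name,
      mechanism_type = mech$mechanism_type, parameter = name,
      requested_part = paste(part_ids, collapse = "|"),
      matched_key = key_string(hit$key$mechanism, hit$key$part_id, name),
      tier = if (is.na(hit$tier)) NA_integer_ else as.integer(hit$tier),
      value = hit$value, source = source, provenance = hit$provenance))
  }
  hit$value
}

# resolve every parameter a mechanism needs (required + optional)
resolve_mech_params <- function(component, mixture_db, mech,
                                extra_part_ids = character(), ctx = NULL) {
  vals <- vapply(mech$param_names, function(nm) {
    resolve_parameter(component, mixture_db, mech, nm,
                      extra_part_ids = extra_part_ids, ctx = ctx)
  }, numeric(1))
  names(vals) <- mech$param_names
  for (nm in names(mech$optional_params)) {
    vals[[nm]] <- resolve_parameter(component, mixture_db, mech, nm,
                                    extra_part_ids = extra_part_ids,
                                    default = mech$optional_params[[nm]],
                                    ctx = ctx)
  }
  vals
}

#' Generate a component's species and reactions
#'
#' The compilation workhorse, dispatched on component type. Each method
#' resolves the mechanisms it needs (local first, then mixture), resolves
#' their parameters (component database first, then mixture database, with
#' the component name as `part_id`) and calls the mechanism updates.
#'
#' @param component A `crn_component`.
#' @param ctx A compile context (mixture mechanism map + parameter database).
#' @return `list(species, reactions)`.
#' @export
component_update <- function(component, ctx) {
  UseMethod("component_update")
}

#' @export
component_update.default <- function(component, ctx) {
  stop("no update method for component type ", sQuote(component$type),
       call. = FALSE)
}

combine_updates <- function(...) {
  parts <- list(...)
  mech_out(do.call(c, lapply(parts, `[[`, "species")),
           do.call(c, lapply(parts, `[[`, "reactions")))
}

# ---- DNA assembly ----------------------------------------------------------

#' DNA assembly component
#'
#' Bundles a promoter, a ribosome binding site and a coding sequence into
#' one expressible unit. The assembly always emits a DNA species named after
#' itself; transcription is emitted iff a promoter is set, translation iff
#' both an RBS and a protein are set. Transcript and protein species default
#' to the assembly name with `rna` / `protein` material, mirroring the
#' DNA/RNA/protein triple of a single expressed gene.
#'
#' For Hill-regulated transcription, set `regulator` (a species or a name,
#' coerced to a protein species) and store/resolve a Hill transcription
#' mechanism; the mechanism's mode decides repression vs activation.
#'
#' @param name Assembly (and emitted DNA species) name.
#' @param promoter,rbs Part names (`NULL` = absent). Used as secondary
#'   `part_id` candidates for transcription / translation parameters.
#' @param protein Product protein name (`NULL` = no translation).
#' @param transcript Transcript name, defaulting to the assembly name.
#' @param regulator Optional regulator for Hill transcription.
#' @param mechanisms,parameters,enumerators Local overrides, see
#'   [crn_component()].
#' @return A `crn_dna_assembly` component.
#' @examples
#' dna_assembly("X", promoter = "prom", rbs = "rbs", protein = "X")
#' @export
dna_assembly <- function(name, promoter = NULL, rbs = NULL, protein = NULL,
                         transcript = name, regulator = NULL,
                         mechanisms = list(), parameters = NULL,
                         enumerators = list()) {
  if (!is.null(regulator)) regulator <- as_crn_species(regulator, "protein")
  crn_component(name, "dna_assembly", mechanisms = mechanisms,
                parameters = parameters, enumerators = enumerators,
                promoter = promoter, rbs = rbs, protein = protein,
                transcript = transcript, regulator = regulator)
}

#' @export
component_update.crn_dna_assembly <- function(component, ctx) {
  dna <- crn_species(component$name, "dna")
  out <- mech_out(list(dna), list())
  transcript_sp <- crn_species(component$transcript %||% component$name,
                               "rna")
  if (!is.null(component$promoter)) {
    mech <- resolve_mechanism(component, ctx$mechanisms, "transcription",
                              ctx = ctx)
    params <- resolve_mech_params(component, ctx$parameters, mech,
                                  extra_part_ids = component$promoter,
                                  ctx = ctx)
    tx <- mech$update(mech, list(dna = dna, transcript = transcript_sp,
                                 regulator = component$regulator), params)
    out <- combine_updates(out, tx)
  }
  if (!is.null(component$rbs)) {
    if (is.null(component$protein)) {
      stop("component ", sQuote(component$name),
           ": rbs is set but no protein product is named", call. = FALSE)
    }
    mech <- resolve_mechanism(component, ctx$mechanisms, "translation",
                              ctx = ctx)
    params <- resolve_mech_params(component, ctx$parameters, mech,
                                  extra_part_ids = component$rbs, ctx = ctx)
    protein_sp <- crn_species(component$protein, "protein")
    tl <- mech$update(mech, list(rna = transcript_sp, protein = protein_sp),
                      params)
    out <- combine_updates(out, tl)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- enzyme ----------------------------------------------------------------

#' Enzyme component
#'
#' Represents an enzyme converting a substrate into a product through a
#' catalysis-type mechanism (Michaelis–Menten by default). The enzyme
#' species is a protein named after the component; substrate and product
#' references given as bare names are auto-created as untyped species.
#'
#' @param name Enzyme name.
#' @param substrate,product Species or names.
#' @inheritParams dna_assembly
#' @return A `crn_enzyme` component.
#' @export
enzyme_component <- function(name, substrate, product, mechanisms = list(),
                             parameters = NULL, enumerators = list()) {
  crn_component(name, "enzyme", mechanisms = mechanisms,
                parameters = parameters, enumerators = enumerators,
                substrate = as_crn_species(substrate),
                product = as_crn_species(product))
}

#' @export
component_update.crn_enzyme <- function(component, ctx) {
  mech <- resolve_mechanism(component, ctx$mechanisms, "catalysis",
                            ctx = ctx)
  params <- resolve_mech_params(component, ctx$parameters, mech, ctx = ctx)
  enzyme_sp <- crn_species(component$name, "protein")
  mech$update(mech, list(enzyme = enzyme_sp, substrate = component$substrate,
                         product = component$product), params)
}

# ---- chemical complex ------------------------------------------------------

#' Chemical complex component
#'
#' Represents species that bind together, through a binding-type mechanism
#' (single-step by default: all members associate in one reversible
#' reaction, so a homotetramer forms as `4A <-> A:A:A:A`). Members may be
#' species, bare names (auto-created untyped), or a named integer vector of
#' multiplicities (`c(A = 4)`).
#'
#' @param name Component name.
#' @param members Member specification (resolved multiset must have >= 2
#'   members).
#' @inheritParams dna_assembly
#' @return A `crn_chemical_complex` component.
#' @export
chemical_complex <- function(name, members, mechanisms = list(),
                             parameters = NULL, enumerators = list()) {
  members <- expand_members(members)
  if (length(members) < 2L) {
    stop("a chemical complex needs at least 2 members", call. = FALSE)
  }
  crn_component(name, "chemical_complex", mechanisms = mechanisms,
                parameters = parameters, enumerators = enumerators,
                members = members)
}

expand_members <- function(members) {
  if (is.numeric(members) && !is.null(names(members))) {
    out <- list()
    for (nm in names(members)) {
      out <- c(out, rep(list(crn_species(nm)), members[[nm]]))
    }
    return(out)
  }
  if (inherits(members, "crn_species")) members <- list(members)
  if (is.character(members)) members <- as.list(members)
  lapply(members, as_crn_species)
}

#' @export
component_update.crn_chemical_complex <- function(component, ctx) {
  mech <- resolve_mechanism(component, ctx$mechanisms, "binding", ctx = ctx)
  params <- resolve_mech_params(component, ctx$parameters, mech, ctx = ctx)
  mech$update(mech, list(members = component$members), params)
}

# ---- component registry ----------------------------------------------------

#' Component registry
#'
#' Model-specification files instantiate components by registered type name
#' (`"dna_assembly"`, `"enzyme"`, `"chemical_complex"`, `"dna_construct"`).
#' User code can register further constructors.
#'
#' @param type Registered type name.
#' @param constructor Function whose first argument is the component name.
#' @return `register_component` returns `type` invisibly;
#'   `registered_components` the sorted names; `get_component_constructor`
#'   the constructor function.
#' @export
register_component <- function(type, constructor) {
  stopifnot(is.character(type), is.function(constructor))
  .registries$components[[type]] <- constructor
  invisible(type)
}

#' @rdname register_component
#' @export
registered_components <- function() sort_c(names(.registries$components))

#' @rdname register_component
#' @export
get_component_constructor <- function(type) {
  ctor <- .registries$components[[type]]
  if (is.null(ctor)) {
    stop("unknown component type ", sQuote(type), "; registered: ",
         paste(registered_components(), collapse = ", "), call. = FALSE)
  }
  ctor
}

register_builtin_components <- function() {
  register_component("dna_assembly", dna_assembly)
  register_component("enzyme", enzyme_component)
  register_component("chemical_complex", chemical_complex)
  register_component("dna_construct", dna_construct)
}
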