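MIXTURE_KINDS <- c("expression_simple", "expression_mm", "txtl_machinery",
                   "custom")

#' Parse a declarative model specification
#'
#' A model spec is a YAML document that mirrors the programmatic API: a
#' mixture (library kind or `custom`), component declarations instantiated
#' through the component registry, mechanism selections by registered name
#' (mixture-level and per-component), parameter files plus inline values,
#' and initial concentrations. The resulting mixture compiles exactly as the
#' equivalent API calls would.
#'
#' ```yaml
#' mixture: {name: mixture, kind: expression_simple}
#' components:
#'   - type: dna_assembly
#'     name: X
#'     promoter: prom
#'     rbs: rbs
#'     protein: X
#' parameters:
#'   inline: {kb: 100, ku: 10, ktx: 0.1, ktl: 0.5}
#' initial_concentrations: {dna_X: 1}
#' ```
#'
#' Mechanism overrides go under a top-level `mechanisms:` map (mechanism
#' type to registered name) or a per-component `mechanisms:` map; parameter
#' files are listed under `parameters: files:` and resolved relative to the
#' spec file. All unresolvable names (mixture kind, component types,
#' mechanism names) are collected and reported in a single error.
#'
#' @param path Path to the YAML model spec.
#' @return A `crn_mixture` ready for [compile_crn()].
#' @export
parse_model_spec <- function(path) {
  if (!file.exists(path)) {
    stop("model spec not found: ", path, call. = FALSE)
  }
  spec <- yaml::read_yaml(path)
  base_dir <- dirname(normalizePath(path))
  unknowns <- character()

  mix <- spec$mixture %||% list()
  kind <- mix$kind %||% "custom"
  mix_name <- mix$name %||% "mixture"
  if (!kind %in% MIXTURE_KINDS) {
    unknowns <- c(unknowns, paste0("mixture kind ", sQuote(kind)))
  }
  # mechanism names (mixture-level and per-component) against the registry
  mech_name_of <- function(x) if (is.list(x)) x$name else as.character(x)
  for (m in spec$mechanisms) {
    if (!mech_name_of(m) %in% registered_mechanisms()) {
      unknowns <- c(unknowns, paste0("mechanism ", sQuote(mech_name_of(m))))
    }
  }
  for (comp in spec$components) {
    if (is.null(comp$type) ||
        !comp$type %in% registered_components()) {
      unknowns <- c(unknowns,
                    paste0("component type ",
                           sQuote(comp$type %||% "(missing)")))
    }
    for (m in comp$mechanisms) {
      if (!mech_name_of(m) %in% registered_mechanisms()) {
        unknowns <- c(unknowns, paste0("mechanism ",
                                       sQuote(mech_name_of(m))))
      }
    }
  }
  files <- as.character(spec$parameters$files %||% character())
  paths <- if (length(files)) {
    ifelse(grepl("^/", files), files, file.path(base_dir, files))
  } else character()
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    unknowns <- c(unknowns, paste0("parameter file ", sQuote(missing_files)))
  }
  if (length(unknowns)) {
    stop("model spec ", path, " has unresolved references:\n  ",
         paste(unique(unknowns), collapse = "\n  "), call. = FALSE)
  }

  # parameters: files first, inline overrides, then initial concentrations
  dbs <- lapply(paths, load_parameter_file)
  db <- if (length(dbs)) do.call(merge_parameter_db, dbs) else parameter_db()
  inline <- spec$parameters$inline
  if (!is.null(inline)) {
    db <- merge_parameter_db(db, parameter_db(unlist(inline),
                                              provenance = "spec:inline"))
  }
  ic <- spec$initial_concentrations
  if (!is.null(ic)) {
    db <- merge_parameter_db(db, parameter_db(tibble::tibble(
      mechanism = NA_character_, part_id = names(ic),
      name = "initial_concentration", value = as.numeric(unlist(ic)),
      provenance = "spec:initial_concentrations")))
  }

  components <- lapply(spec$components, build_spec_component)

  depth <- mix$max_enumeration_depth %||% 8L
  if (kind == "custom") {
    mechs <- build_mechanism_map(spec$mechanisms)
    mixture <- crn_mixture(mix_name, components = components,
                           mechanisms = mechs, parameters = db,
                           max_enumeration_depth = depth)
  } else {
    mixture <- make_library_mixture(kind, parameters = db,
                                    components = components,
                                    name = mix_name,
                                    max_enumeration_depth = depth)
    if (!is.null(spec$mechanisms)) {
      overrides <- build_mechanism_map(spec$mechanisms)
      for (tp in names(overrides)) {
        mixture$mechanisms[[tp]] <- overrides[[tp]]
      }
    }
  }
  mixture
}

# a mechanisms: map may key by type explicitly or rely on each mechanism's
# own type; entries are registered names
build_mechanism_map <- function(entries) {
  if (is.null(entries)) return(list())
  mechs <- lapply(entries, function(m) get_mechanism(
    if (is.list(m)) m$name else as.character(m)))
  if (!is.null(names(entries)) && all(nzchar(names(entries)))) {
    names(mechs) <- names(entries)
    return(mechs)
  }
  key_mechanisms(mechs)
}

build_spec_component <- function(decl) {
  ctor <- get_component_constructor(decl$type)
  args <- decl[setdiff(names(decl), c("type", "mechanisms", "parameters"))]
  if (!is.null(decl$mechanisms)) {
    args$mechanisms <- build_mechanism_map(decl$mechanisms)
  }
  if (!is.null(decl$parameters)) {
    args$parameters <- unlist(decl$parameters)
  }
  known <- names(formals(ctor))
  bad <- setdiff(names(args), known)
  if (length(bad)) {
    stop("component ", sQuote(decl$name %||% "?"), " (", decl$type,
         ") has unknown field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(ctor, args)
}
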