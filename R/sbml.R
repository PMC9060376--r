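SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
ANN_NS <- "https://crnforge.invalid/annotation"

#' Sanitize a string into a legal SBML identifier
#'
#' SBML SIds must match `[A-Za-z_][A-Za-z0-9_]*`. Canonical species names are
#' already underscore-joined; any remaining illegal character is replaced by
#' an `_x<hex>_` escape (injective: distinct inputs give distinct ids) and a
#' leading digit gets an underscore prefix.
#'
#' @param name Non-empty string.
#' @return A legal SId string.
#' @examples
#' sanitize_id("dna_X")  # unchanged
#' sanitize_id("2X")     # "_2X"
#' @export
sanitize_id <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("cannot sanitize an empty id", call. = FALSE)
  }
  chars <- strsplit(name, "")[[1L]]
  legal <- grepl("^[A-Za-z0-9_]$", chars)
  chars[!legal] <- vapply(chars[!legal], function(c)
    sprintf("_x%02x_", utf8ToInt(c)), character(1))
  out <- paste(chars, collapse = "")
  if (!grepl("^[A-Za-z_]", out)) out <- paste0("_", out)
  out
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# ---- MathML ----------------------------------------------------------------

MATHML_OPS <- c("+" = "plus", "-" = "minus", "*" = "times", "/" = "divide",
                "^" = "power", "exp" = "exp", "log" = "ln", "sqrt" = "root",
                "abs" = "abs", "min" = "min", "max" = "max")

# R expression AST -> MathML lines. symmap maps symbol names to ci text.
mathml_from_expr <- function(e, symmap, indent) {
  pad <- strrep(" ", indent)
  if (is.numeric(e)) {
    if (e == round(e) && abs(e) < 1e15) {
      return(sprintf('%s<cn type="integer">%d</cn>', pad, as.integer(e)))
    }
    return(sprintf('%s<cn type="real">%s</cn>', pad, fmt_num(e)))
  }
  if (is.name(e)) {
    nm <- as.character(e)
    mapped <- symmap[[nm]]
    if (is.null(mapped)) {
      stop("unknown symbol ", sQuote(nm), " in rate expression",
           call. = FALSE)
    }
    return(sprintf("%s<ci> %s </ci>", pad, mapped))
  }
  if (is.call(e)) {
    fn <- as.character(e[[1L]])
    if (fn == "(") return(mathml_from_expr(e[[2L]], symmap, indent))
    op <- MATHML_OPS[[fn]]
    if (is.null(op)) {
      stop("operator ", sQuote(fn), " not supported in MathML export",
           call. = FALSE)
    }
    args <- lapply(seq_along(e)[-1L], function(i)
      mathml_from_expr(e[[i]], symmap, indent + 2L))
    return(paste(c(sprintf("%s<apply>", pad), sprintf("%s  <%s/>", pad, op),
                   unlist(args), sprintf("%s</apply>", pad)),
                 collapse = "\n"))
  }
  stop("cannot convert expression to MathML", call. = FALSE)
}

symbols_in_expr <- function(e) {
  if (is.name(e)) return(as.character(e))
  if (is.call(e)) {
    return(unique(unlist(lapply(seq_along(e)[-1L], function(i)
      symbols_in_expr(e[[i]])))))
  }
  character()
}

# ---- species annotation (lossless structure round trip) --------------------

species_annotation <- function(sp, indent) {
  pad <- strrep(" ", indent)
  if (!is_complex(sp)) {
    sprintf('%s<cf:simple name="%s" material="%s" attributes="%s"/>',
            pad, xml_escape(sp$name), sp$material,
            xml_escape(paste(sp$attributes, collapse = ",")))
  } else {
    paste(c(sprintf('%s<cf:complex attributes="%s">', pad,
                    xml_escape(paste(sp$attributes, collapse = ","))),
            vapply(sp$members, species_annotation, character(1),
                   indent = indent + 2L),
            sprintf("%s</cf:complex>", pad)), collapse = "\n")
  }
}

species_from_annotation <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "simple") {
    attrs <- xml2::xml_attr(node, "attributes")
    attrs <- if (is.na(attrs) || !nzchar(attrs)) character()
             else strsplit(attrs, ",", fixed = TRUE)[[1L]]
    crn_species(xml2::xml_attr(node, "name"),
                xml2::xml_attr(node, "material"), attributes = attrs)
  } else if (nm == "complex") {
    attrs <- xml2::xml_attr(node, "attributes")
    attrs <- if (is.na(attrs) || !nzchar(attrs)) character()
             else strsplit(attrs, ",", fixed = TRUE)[[1L]]
    crn_complex(lapply(xml2::xml_children(node), species_from_annotation),
                attributes = attrs)
  } else {
    stop("unknown species annotation node ", nm, call. = FALSE)
  }
}

# ---- export ----------------------------------------------------------------

#' Export a CRN as SBML Level 3 Version 1
#'
#' Writes a single-compartment SBML core document: one species per network
#' species (id = [sanitize_id()] of the canonical name, initial concentration
#' from `initial`, default 0) and one irreversible reaction per network
#' reaction. Mass-action kinetic laws are written as `k` times the reactant
#' concentrations with `k` a local parameter; Hill and general propensities
#' are written as explicit MathML rate formulas over global (Hill) or local
#' (general-expression constants) parameters, with regulators declared as
#' modifiers — no non-core packages are used, so any SBML L3 simulator can
#' run the model. Structured annotations record the species structure and
#' propensity payload, which is what makes [read_sbml()] lossless and the
#' export/import/re-export cycle byte-identical. The serialization itself is
#' deterministic.
#'
#' @param crn A `crn`.
#' @param initial Named numeric vector of initial concentrations keyed by
#'   canonical species name; defaults to the `initial` attribute attached by
#'   [compile_crn()], else all zero.
#' @param path Optional output file path.
#' @param model_id SBML model id.
#' @return The SBML document as a single string (invisibly when `path` is
#'   given).
#' @export
export_sbml <- function(crn, initial = NULL, path = NULL,
                        model_id = "crnforge_model") {
  stopifnot(inherits(crn, "crn"))
  if (is.null(initial)) initial <- attr(crn, "initial")
  if (is.null(initial)) initial <- numeric()
  canon <- species_names(crn)
  ids <- vapply(canon, sanitize_id, character(1))
  if (anyDuplicated(ids)) {
    stop("SBML id collision after sanitization: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  idmap <- as.list(ids)
  names(idmap) <- canon
  # bare names of simple species map to their id when unambiguous
  bare <- vapply(crn$species, function(s)
    if (is_complex(s)) NA_character_ else s$name, character(1))
  for (nm in unique(bare[!is.na(bare)])) {
    if (sum(bare == nm, na.rm = TRUE) == 1L && is.null(idmap[[nm]])) {
      idmap[[nm]] <- ids[[which(bare == nm)]]
    }
  }

  L <- character()
  add <- function(...) L[[length(L) + 1L]] <<- paste0(...)
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="', SBML_NS, '" xmlns:cf="', ANN_NS,
      '" level="3" version="1">')
  add('  <model id="', sanitize_id(model_id), '">')
  add('    <listOfCompartments>')
  add('      <compartment id="default" spatialDimensions="3" size="1"',
      ' constant="true"/>')
  add('    </listOfCompartments>')
  if (n_species(crn) > 0) {
    add('    <listOfSpecies>')
    for (i in seq_along(crn$species)) {
      sp <- crn$species[[i]]
      conc <- if (canon[[i]] %in% names(initial)) {
        initial[[canon[[i]]]]
      } else 0
      if (is.na(conc)) conc <- 0
      add('      <species id="', ids[[i]], '" compartment="default"',
          ' initialConcentration="', fmt_num(conc), '"',
          ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
          ' constant="false">')
      add('        <annotation>')
      add(species_annotation(sp, 10L))
      add('        </annotation>')
      add('      </species>')
    }
    add('    </listOfSpecies>')
  }
  # global parameters for hill propensities
  gpar <- character()
  for (i in seq_along(crn$reactions)) {
    p <- crn$reactions[[i]]$propensity
    if (p$kind %in% c("hill_positive", "hill_negative")) {
      rid <- paste0("r", i)
      for (nm in c("k", "K", "n")) {
        gpar <- c(gpar, sprintf(
          '      <parameter id="%s_%s" value="%s" constant="true"/>',
          nm, rid, fmt_num(p$parameters[[nm]])))
      }
    }
  }
  if (length(gpar)) {
    add('    <listOfParameters>')
    for (g in gpar) add(g)
    add('    </listOfParameters>')
  }
  if (n_reactions(crn) > 0) {
    add('    <listOfReactions>')
    for (i in seq_along(crn$reactions)) {
      add(reaction_sbml(crn$reactions[[i]], paste0("r", i), idmap))
    }
    add('    </listOfReactions>')
  }
  add('  </model>')
  add('</sbml>')
  doc <- paste0(paste(L, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(doc, path, sep = "")
    return(invisible(doc))
  }
  doc
}

reaction_sbml <- function(r, rid, idmap) {
  in_tab <- stoich_table(r$inputs)
  out_tab <- stoich_table(r$outputs)
  p <- r$propensity
  L <- character()
  add <- function(...) L[[length(L) + 1L]] <<- paste0(...)
  add('      <reaction id="', rid, '" reversible="false">')
  add('        <annotation>')
  add('          ', propensity_annotation(p))
  add('        </annotation>')
  ref <- function(tab, tag, listtag) {
    if (length(tab) == 0L) return()
    add('        <', listtag, '>')
    for (j in seq_along(tab)) {
      add('          <', tag, ' species="', idmap[[names(tab)[j]]],
          '" stoichiometry="', fmt_num(as.numeric(tab[[j]])),
          '" constant="true"/>')
    }
    add('        </', listtag, '>')
  }
  ref(in_tab, "speciesReference", "listOfReactants")
  ref(out_tab, "speciesReference", "listOfProducts")
  # modifiers: species the rate references that are not reactants
  mods <- character()
  for (sp in propensity_species(p)) {
    key <- canonical_name(sp)
    if (!key %in% names(in_tab)) mods <- c(mods, idmap[[key]])
  }
  if (p$kind == "general") {
    for (sym in symbols_in_expr(str2lang(p$expression))) {
      if (sym %in% names(p$parameters)) next
      id <- idmap[[sym]]
      if (is.null(id)) {
        stop("rate expression references unknown species ", sQuote(sym),
             call. = FALSE)
      }
      if (!id %in% vapply(names(in_tab), function(k) idmap[[k]],
                          character(1))) {
        mods <- c(mods, id)
      }
    }
  }
  mods <- unique(mods)
  if (length(mods)) {
    add('        <listOfModifiers>')
    for (m in mods) {
      add('          <modifierSpeciesReference species="', m, '"/>')
    }
    add('        </listOfModifiers>')
  }
  add('        <kineticLaw>')
  add('          <math xmlns="', MATHML_NS, '">')
  add(kinetic_math(p, rid, in_tab, idmap, 12L))
  add('          </math>')
  lp <- local_params(p)
  if (length(lp)) {
    add('          <listOfLocalParameters>')
    for (nm in names(lp)) {
      add('            <localParameter id="', nm, '" value="',
          fmt_num(lp[[nm]]), '"/>')
    }
    add('          </listOfLocalParameters>')
  }
  add('        </kineticLaw>')
  add('      </reaction>')
  paste(L, collapse = "\n")
}

local_params <- function(p) {
  switch(p$kind,
         massaction = c(k = unname(p$parameters[["k"]])),
         general = p$parameters,
         numeric())
}

# direct MathML node builders (used where symbols are SBML ids, which need
# not be valid R symbols)
ml_ci <- function(id) structure(list(id = id), class = "ml_ci")
ml_cn <- function(x) structure(list(x = x), class = "ml_cn")
ml_apply <- function(op, ...) {
  structure(list(op = op, args = list(...)), class = "ml_apply")
}

ml_render <- function(node, indent) {
  pad <- strrep(" ", indent)
  if (inherits(node, "ml_ci")) {
    return(sprintf("%s<ci> %s </ci>", pad, node$id))
  }
  if (inherits(node, "ml_cn")) {
    x <- node$x
    if (x == round(x) && abs(x) < 1e15) {
      return(sprintf('%s<cn type="integer">%d</cn>', pad, as.integer(x)))
    }
    return(sprintf('%s<cn type="real">%s</cn>', pad, fmt_num(x)))
  }
  paste(c(sprintf("%s<apply>", pad), sprintf("%s  <%s/>", pad, node$op),
          vapply(node$args, ml_render, character(1), indent = indent + 2L),
          sprintf("%s</apply>", pad)), collapse = "\n")
}

kinetic_math <- function(p, rid, in_tab, idmap, indent) {
  switch(
    p$kind,
    massaction = {
      terms <- list(ml_ci("k"))
      for (j in seq_along(in_tab)) {
        ci <- ml_ci(idmap[[names(in_tab)[j]]])
        terms <- c(terms, list(
          if (in_tab[[j]] > 1L) {
            ml_apply("power", ci, ml_cn(as.numeric(in_tab[[j]])))
          } else ci))
      }
      node <- if (length(terms) == 1L) terms[[1L]]
              else do.call(ml_apply, c(list("times"), terms))
      ml_render(node, indent)
    },
    hill_positive = ,
    hill_negative = {
      r_ci <- ml_ci(idmap[[canonical_name(p$regulator)]])
      kk <- ml_ci(paste0("k_", rid))
      KK <- ml_ci(paste0("K_", rid))
      nn <- ml_ci(paste0("n_", rid))
      Kn <- ml_apply("power", KK, nn)
      rn <- ml_apply("power", r_ci, nn)
      numer_tail <- if (p$kind == "hill_positive") rn else Kn
      numer_terms <- c(list(kk),
                       if (!is.null(p$scaling)) {
                         list(ml_ci(idmap[[canonical_name(p$scaling)]]))
                       },
                       list(numer_tail))
      numer <- do.call(ml_apply, c(list("times"), numer_terms))
      denom <- ml_apply("plus", Kn, rn)
      ml_render(ml_apply("divide", numer, denom), indent)
    },
    general = {
      symmap <- idmap
      for (nm in names(p$parameters)) symmap[[nm]] <- nm
      mathml_from_expr(str2lang(p$expression), symmap, indent)
    }
  )
}

propensity_annotation <- function(p) {
  switch(
    p$kind,
    massaction = sprintf('<cf:propensity kind="massaction" k="%s"/>',
                         fmt_num(p$parameters[["k"]])),
    hill_positive = ,
    hill_negative = {
      sprintf(paste0('<cf:propensity kind="%s" k="%s" K="%s" n="%s"',
                     ' regulator="%s"%s/>'),
              p$kind, fmt_num(p$parameters[["k"]]),
              fmt_num(p$parameters[["K"]]), fmt_num(p$parameters[["n"]]),
              xml_escape(canonical_name(p$regulator)),
              if (!is.null(p$scaling)) {
                sprintf(' scaling="%s"', xml_escape(canonical_name(p$scaling)))
              } else "")
    },
    general = {
      consts <- paste(vapply(names(p$parameters), function(nm)
        sprintf(' %s="%s"', nm, fmt_num(p$parameters[[nm]])), character(1)),
        collapse = "")
      sprintf('<cf:propensity kind="general" expression="%s"%s/>',
              xml_escape(p$expression), consts)
    }
  )
}

# ---- import ----------------------------------------------------------------

#' Read an SBML document written by this package
#'
#' Reconstructs the CRN (species structure and propensities come from the
#' structured annotations; stoichiometries from the reactant/product lists)
#' and the initial concentrations. `export_sbml(read_sbml(f))` reproduces
#' `f` byte-identically.
#'
#' @param path File path or an SBML document string.
#' @return A list with `crn`, `initial` (named numeric) and `model_id`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, cf = ANN_NS)
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  species <- list()
  initial <- numeric()
  by_id <- list()
  for (node in sp_nodes) {
    ann <- xml2::xml_find_first(
      node, "./s:annotation/*[local-name()='simple' or local-name()='complex']",
      ns)
    if (is.na(ann)) {
      stop("species ", xml2::xml_attr(node, "id"),
           " lacks a structure annotation; not written by this package",
           call. = FALSE)
    }
    sp <- species_from_annotation(ann)
    species[[length(species) + 1L]] <- sp
    by_id[[xml2::xml_attr(node, "id")]] <- sp
    initial[[canonical_name(sp)]] <-
      as.numeric(xml2::xml_attr(node, "initialConcentration"))
  }
  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  reactions <- lapply(rx_nodes, function(node) {
    side <- function(xp) {
      refs <- xml2::xml_find_all(node, xp, ns)
      out <- list()
      for (ref in refs) {
        sp <- by_id[[xml2::xml_attr(ref, "species")]]
        k <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
        out <- c(out, rep(list(sp), k))
      }
      out
    }
    ann <- xml2::xml_find_first(
      node, "./s:annotation/*[local-name()='propensity']", ns)
    if (is.na(ann)) {
      stop("reaction ", xml2::xml_attr(node, "id"),
           " lacks a propensity annotation", call. = FALSE)
    }
    crn_reaction(side("./s:listOfReactants/s:speciesReference"),
                 side("./s:listOfProducts/s:speciesReference"),
                 propensity_from_annotation(ann, by_id))
  })
  crn <- assemble_crn(species, reactions, warn = FALSE)
  list(crn = crn, initial = initial,
       model_id = xml2::xml_attr(model, "id"))
}

propensity_from_annotation <- function(ann, by_id) {
  kind <- xml2::xml_attr(ann, "kind")
  species_by_canon <- list()
  for (sp in by_id) species_by_canon[[canonical_name(sp)]] <- sp
  if (kind == "massaction") {
    massaction(as.numeric(xml2::xml_attr(ann, "k")))
  } else if (kind %in% c("hill_positive", "hill_negative")) {
    reg <- species_by_canon[[xml2::xml_attr(ann, "regulator")]]
    sc_attr <- xml2::xml_attr(ann, "scaling")
    sc <- if (!is.na(sc_attr)) species_by_canon[[sc_attr]]
    hill_propensity(kind, as.numeric(xml2::xml_attr(ann, "k")),
                    as.numeric(xml2::xml_attr(ann, "K")),
                    as.numeric(xml2::xml_attr(ann, "n")), reg, sc)
  } else if (kind == "general") {
    attrs <- xml2::xml_attrs(ann)
    cn <- setdiff(names(attrs), c("kind", "expression"))
    consts <- as.numeric(attrs[cn])
    names(consts) <- cn
    general_propensity(attrs[["expression"]], consts)
  } else {
    stop("unknown propensity kind in annotation: ", kind, call. = FALSE)
  }
}

# ---- validation ------------------------------------------------------------

#' Check an SBML document for structural consistency
#'
#' Validates the constraints of SBML Level 3 Version 1 core that a
#' rate-model consumer depends on: well-formed XML in the right namespace
#' and level/version; unique, grammar-legal SIds; species referencing an
#' existing compartment and carrying the required attribute set; reaction
#' species references resolving to declared species; an explicit
#' `reversible` flag on every reaction; and every `<ci>` symbol in every
#' kinetic law resolving to a species, global parameter, local parameter or
#' compartment id.
#'
#' @param x A file path or SBML document string.
#' @return Character vector of problems; empty when the document is
#'   consistent.
#' @export
validate_sbml <- function(x) {
  problems <- character()
  doc <- tryCatch(xml2::read_xml(x), error = function(e) e)
  if (inherits(doc, "error")) {
    return(paste("not well-formed XML:", conditionMessage(doc)))
  }
  ns <- c(s = SBML_NS)
  root <- xml2::xml_name(doc)
  if (root != "sbml" || !identical(xml2::xml_ns(doc)[["d1"]], SBML_NS)) {
    problems <- c(problems, "root element is not SBML L3V1 core <sbml>")
  }
  if (!identical(xml2::xml_attr(doc, "level"), "3") ||
      !identical(xml2::xml_attr(doc, "version"), "1")) {
    problems <- c(problems, "level/version attributes are not 3/1")
  }
  model <- xml2::xml_find_all(doc, "./s:model", ns)
  if (length(model) != 1L) {
    return(c(problems, "document must contain exactly one <model>"))
  }
  sid_ok <- function(x) grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)
  comp_ids <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:listOfCompartments/s:compartment", ns), "id")
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_ids <- xml2::xml_attr(sp_nodes, "id")
  par_ids <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:model/s:listOfParameters/s:parameter", ns),
    "id")
  all_ids <- c(comp_ids, sp_ids, par_ids)
  if (any(!sid_ok(all_ids))) {
    problems <- c(problems, paste("illegal SId(s):",
                                  paste(all_ids[!sid_ok(all_ids)],
                                        collapse = ", ")))
  }
  if (anyDuplicated(all_ids)) {
    problems <- c(problems, paste("duplicated SId(s):",
                                  paste(unique(all_ids[duplicated(all_ids)]),
                                        collapse = ", ")))
  }
  for (node in sp_nodes) {
    id <- xml2::xml_attr(node, "id")
    if (!xml2::xml_attr(node, "compartment") %in% comp_ids) {
      problems <- c(problems,
                    paste0("species ", id, " references unknown compartment"))
    }
    for (req in c("hasOnlySubstanceUnits", "boundaryCondition", "constant")) {
      if (is.na(xml2::xml_attr(node, req))) {
        problems <- c(problems,
                      paste0("species ", id, " lacks required attribute ",
                             req))
      }
    }
  }
  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rx_ids <- xml2::xml_attr(rx_nodes, "id")
  if (anyDuplicated(rx_ids)) {
    problems <- c(problems, "duplicated reaction id(s)")
  }
  for (node in rx_nodes) {
    id <- xml2::xml_attr(node, "id")
    if (is.na(xml2::xml_attr(node, "reversible"))) {
      problems <- c(problems,
                    paste0("reaction ", id, " lacks the reversible flag"))
    }
    refs <- xml2::xml_find_all(
      node, ".//s:speciesReference | .//s:modifierSpeciesReference", ns)
    for (ref in refs) {
      s <- xml2::xml_attr(ref, "species")
      if (!s %in% sp_ids) {
        problems <- c(problems, paste0("reaction ", id,
                                       " references unknown species ", s))
      }
    }
    local_ids <- xml2::xml_attr(
      xml2::xml_find_all(node, ".//s:localParameter", ns), "id")
    cis <- xml2::xml_text(
      xml2::xml_find_all(node,
                         ".//*[local-name()='math']//*[local-name()='ci']"))
    cis <- trimws(cis)
    known <- c(sp_ids, par_ids, local_ids, comp_ids)
    bad <- setdiff(cis, known)
    if (length(bad)) {
      problems <- c(problems,
                    paste0("reaction ", id, " kinetic law references ",
                           "unknown symbol(s): ",
                           paste(bad, collapse = ", ")))
    }
  }
  problems
}

#' @rdname validate_sbml
#' @return `sbml_valid()` returns `TRUE`/`FALSE`.
#' @export
sbml_valid <- function(x) length(validate_sbml(x)) == 0L
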