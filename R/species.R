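#' @importFrom tibble tibble as_tibble
NULL

# Materials recognised by the species grammar. "complex" is reserved for
# complex species and cannot be assigned directly.
CRN_MATERIALS <- c("dna", "rna", "protein", "complex", "small_molecule", "none")

# Tokens that may not be used as species names or attribute tags: they are
# terminals of the canonical-name grammar, and excluding them is what makes
# canonical names parseable (hence injective).
RESERVED_TOKENS <- c("dna", "rna", "protein", "complex", "small_molecule",
                     "small", "molecule", "none")

is_reserved_token <- function(x) {
  x %in% RESERVED_TOKENS | grepl("^complex[0-9]+$", x)
}

check_token <- function(x, what) {
  if (length(x) != 1L || !is.character(x) || is.na(x) || !nzchar(x)) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  if (grepl("[[:space:]_]", x)) {
    stop(what, " ", sQuote(x),
         " may not contain whitespace or the reserved separator '_'",
         call. = FALSE)
  }
  if (is_reserved_token(x)) {
    stop(what, " ", sQuote(x), " is a reserved word of the naming grammar",
         call. = FALSE)
  }
  invisible(x)
}

#' Create a chemical species
#'
#' Species are the atoms of a compiled chemical reaction network. A species is
#' identified by its name, its material type (DNA, RNA, protein, small
#' molecule, or untyped) and an ordered set of attribute tags (free-form
#' labels such as `"degradable"` or `"machinery"` that mechanisms and filters
#' can act on). Two species are equal exactly when all three coincide;
#' equality is implemented through the canonical name, which is injective.
#'
#' Names and attribute tags may not contain whitespace or `_` (the canonical
#' separator) and may not equal reserved grammar tokens (the material-type
#' names, `"complex"`, `"complex<digits>"`, `"small"`, `"molecule"`).
#'
#' @param name Species name, a non-empty string.
#' @param material One of `"dna"`, `"rna"`, `"protein"`, `"small_molecule"`,
#'   `"none"` (default). Use [crn_complex()] to build complexes.
#' @param attributes Character vector of attribute tags; duplicates dropped.
#' @return An object of class `crn_species`.
#' @examples
#' crn_species("X", "dna")
#' crn_species("GFP", "protein", attributes = "degradable")
#' @export
crn_species <- function(name, material = "none", attributes = character()) {
  check_token(name, "species name")
  material <- match.arg(material, CRN_MATERIALS)
  if (material == "complex") {
    stop("material 'complex' is reserved; use crn_complex()", call. = FALSE)
  }
  attributes <- unique(as.character(attributes))
  for (a in attributes) check_token(a, "attribute tag")
  structure(
    list(name = name, material = material,
         attributes = sort_c(attributes), members = NULL),
    class = "crn_species"
  )
}

#' Bind species into a complex
#'
#' Joins two or more species into a complex species. In printed reactions the
#' `:` separator indicates that the members are bound together into a new
#' species. Member order is preserved and nested complexes are kept nested
#' (binding order is information: `A:B` then `:C` is not the same species as
#' the flat three-member complex), so enumeration code can rely on structure.
#'
#' @param members A list of `crn_species` (length >= 2).
#' @param attributes Attribute tags for the complex itself.
#' @return A `crn_complex` object (also a `crn_species`); its material type
#'   is always `"complex"`.
#' @examples
#' G <- crn_species("X", "dna")
#' P <- crn_species("P")
#' crn_complex(list(G, P))   # displayed dna_X:P
#' @export
crn_complex <- function(members, attributes = character()) {
  if (!is.list(members) || length(members) < 2L) {
    stop("a complex needs at least 2 member species", call. = FALSE)
  }
  for (m in members) {
    if (!inherits(m, "crn_species")) {
      stop("all complex members must be crn_species objects", call. = FALSE)
    }
  }
  attributes <- unique(as.character(attributes))
  for (a in attributes) check_token(a, "attribute tag")
  structure(
    list(name = NULL, material = "complex",
         attributes = sort_c(attributes), members = members),
    class = c("crn_complex", "crn_species")
  )
}

#' @rdname crn_complex
#' @param ... Species passed individually instead of as a list.
#' @export
make_complex <- function(..., attributes = character()) {
  members <- list(...)
  if (length(members) == 1L && is.list(members[[1L]]) &&
      !inherits(members[[1L]], "crn_species")) {
    members <- members[[1L]]
  }
  crn_complex(members, attributes = attributes)
}

is_complex <- function(x) inherits(x, "crn_complex")

# Locale-independent lexicographic sort (C collation) so canonical names do
# not depend on the session locale.
sort_c <- function(x) {
  if (length(x) == 0L) return(character())
  x[order(x, method = "radix")]
}

# Canonical-name grammar:
#   simple   := <material> "_" <name> ("_" <attr>)*        attrs sorted
#   complex  := "complex" ("_" <attr>)* ("_" <member>)+     (top level)
#   member   := simple | "complex<N>" ("_" <attr>)* ("_" <member>){N}
# Reserved-token validation plus the arity marker on embedded complexes make
# the grammar unambiguous, so canonical_name is injective over all species.
embed_name <- function(sp, top = FALSE) {
  if (!is_complex(sp)) {
    paste(c(sp$material, sp$name, sp$attributes), collapse = "_")
  } else {
    prefix <- if (top) "complex" else paste0("complex", length(sp$members))
    inner <- vapply(sp$members, embed_name, character(1), top = FALSE)
    paste(c(prefix, sp$attributes, inner), collapse = "_")
  }
}

#' Canonical name of a species
#'
#' The canonical name is a deterministic identifier string: lowercase material
#' prefix, `_`, the species name, then attribute tags sorted lexicographically
#' (`dna_X`, `protein_GFP_degradable`). Complexes use the `complex_` prefix
#' and concatenate their members' canonical names (`complex_dna_X_protein_P`).
#' The mapping is injective: distinct species always receive distinct
#' canonical names, which makes the canonical name usable as the species
#' identity and (after [sanitize_id()]) as an SBML id.
#'
#' @param species A `crn_species`.
#' @return A single string.
#' @examples
#' canonical_name(crn_species("X", "dna"))  # "dna_X"
#' @export
canonical_name <- function(species) {
  stopifnot(inherits(species, "crn_species"))
  embed_name(species, top = TRUE)
}

#' Display form of a species
#'
#' Human-readable form used by the CRN pretty-printer: untyped species print
#' as their bare name, typed species as their canonical name, and complexes
#' join their members' display forms with `:` in member order (the `:`
#' denotes bound-together species).
#'
#' @param species A `crn_species`.
#' @return A single string.
#' @export
species_display <- function(species) {
  stopifnot(inherits(species, "crn_species"))
  if (is_complex(species)) {
    paste(vapply(species$members, species_display, character(1)),
          collapse = ":")
  } else if (species$material == "none") {
    paste(c(species$name, species$attributes), collapse = "_")
  } else {
    canonical_name(species)
  }
}

#' Test species equality
#'
#' Two species are equal iff material type, name and attribute set coincide
#' (for complexes: the ordered member list and attributes). Implemented via
#' canonical names, which are injective.
#'
#' @param a,b `crn_species` objects.
#' @return `TRUE` or `FALSE`.
#' @export
species_equal <- function(a, b) {
  identical(canonical_name(a), canonical_name(b))
}

#' Does a species carry an attribute tag?
#' @param species A `crn_species`.
#' @param attribute Attribute tag string.
#' @return `TRUE` or `FALSE`.
#' @export
has_attribute <- function(species, attribute) {
  attribute %in% species$attributes
}

#' Return a copy of a species with extra attribute tags
#' @param species A `crn_species`.
#' @param attributes Tags to add (validated like in [crn_species()]).
#' @return The modified species.
#' @export
add_attributes <- function(species, attributes) {
  attributes <- unique(as.character(attributes))
  for (a in attributes) check_token(a, "attribute tag")
  species$attributes <- sort_c(unique(c(species$attributes, attributes)))
  species
}

#' @export
print.crn_species <- function(x, ...) {
  cat(species_display(x), " <", canonical_name(x), ">\n", sep = "")
  invisible(x)
}

#' @export
format.crn_species <- function(x, ...) species_display(x)

# Coerce a species reference in user input: an existing crn_species is kept,
# a bare string becomes an untyped species (closure rule for members that are
# never defined elsewhere).
as_crn_species <- function(x, material = "none") {
  if (inherits(x, "crn_species")) return(x)
  if (is.character(x) && length(x) == 1L) return(crn_species(x, material))
  stop("cannot interpret ", deparse(x), " as a species", call. = FALSE)
}
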