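#' Assemble species and reactions into a chemical reaction network
#'
#' The CRN container deduplicates species (by equality) and reactions (by
#' identity: same input/output multisets, propensity kind and parameters),
#' and closes the species set over every species any reaction touches —
#' including regulator and scaling species referenced only by a propensity.
#' First-encountered order is preserved, so reassembling the same inputs
#' always yields a byte-identical serialized network. A warning is emitted
#' for every duplicate dropped.
#'
#' @param species List of `crn_species` (may be empty).
#' @param reactions List of `crn_reaction` (may be empty).
#' @param warn Warn on dropped duplicates (default `TRUE`; the compiler
#'   assembles with `warn = FALSE` because the same species legitimately
#'   arrives from several component updates).
#' @return A `crn` object with fields `species` and `reactions`.
#' @examples
#' X <- crn_species("X", "dna")
#' Y <- crn_species("Y", "rna")
#' assemble_crn(list(), list(crn_reaction(list(X), list(X, Y), 0.1)))
#' @export
assemble_crn <- function(species = list(), reactions = list(), warn = TRUE) {
  species <- normalize_multiset(species, "species")
  if (inherits(reactions, "crn_reaction")) reactions <- list(reactions)
  for (r in reactions) {
    if (!inherits(r, "crn_reaction")) {
      stop("all reactions must be crn_reaction objects", call. = FALSE)
    }
  }
  sp_out <- list(); sp_keys <- character()
  add_species <- function(s, warn_dup = FALSE) {
    key <- canonical_name(s)
    if (key %in% sp_keys) {
      if (warn_dup && warn) {
        warning("duplicate species dropped: ", key, call. = FALSE)
      }
      return(invisible(NULL))
    }
    sp_keys[[length(sp_keys) + 1L]] <<- key
    sp_out[[length(sp_out) + 1L]] <<- s
    invisible(NULL)
  }
  for (s in species) add_species(s, warn_dup = TRUE)

  rx_out <- list(); rx_keys <- character()
  for (r in reactions) {
    key <- reaction_serial(r)
    if (key %in% rx_keys) {
      if (warn) {
        warning("duplicate reaction dropped: ", reaction_display(r),
                call. = FALSE)
      }
      next
    }
    rx_keys <- c(rx_keys, key)
    rx_out[[length(rx_out) + 1L]] <- r
    for (s in reaction_species(r)) add_species(s)
  }
  structure(list(species = sp_out, reactions = rx_out), class = "crn")
}

#' Number of species / reactions in a CRN
#' @param crn A `crn` object.
#' @return An integer.
#' @export
n_species <- function(crn) length(crn$species)

#' @rdname n_species
#' @export
n_reactions <- function(crn) length(crn$reactions)

#' Canonical names of all species in a CRN
#' @param crn A `crn` object.
#' @return Character vector in network order.
#' @export
species_names <- function(crn) {
  vapply(crn$species, canonical_name, character(1))
}

#' Serialize a CRN as plain text
#'
#' One species per line in a header block, then one reaction per line in the
#' `A + B --k--> C` pretty-printer format. The output is deterministic and is
#' what the golden-file tests diff against.
#'
#' @param crn A `crn` object.
#' @param path Optional file path; if given the text is written there.
#' @return Character vector of lines, invisibly when `path` is given.
#' @export
write_crn_text <- function(crn, path = NULL) {
  lines <- c(
    paste0("# species (", n_species(crn), ")"),
    vapply(crn$species, function(s)
      paste0(species_display(s), "\t", canonical_name(s)), character(1)),
    paste0("# reactions (", n_reactions(crn), ")"),
    vapply(crn$reactions, reaction_display, character(1))
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Export the species/reaction bipartite graph as an edge list
#'
#' Writes one edge per line, `tail -> head`, where reaction nodes are labeled
#' `r<i>` in network order. An edge `S -> r3` means species S is consumed (or
#' modulates, for propensity roles) and `r3 -> S` means S is produced. This
#' plain-text export replaces interactive graph rendering and loads directly
#' into standard graph tools.
#'
#' @param crn A `crn` object.
#' @param path Optional file path.
#' @return Character vector of edge lines, invisibly when `path` is given.
#' @export
write_crn_graph <- function(crn, path = NULL) {
  lines <- character()
  for (i in seq_along(crn$reactions)) {
    r <- crn$reactions[[i]]
    rid <- paste0("r", i)
    for (s in r$inputs) {
      lines <- c(lines, paste(canonical_name(s), "->", rid))
    }
    for (s in propensity_species(r$propensity)) {
      lines <- c(lines, paste(canonical_name(s), "->", rid))
    }
    for (s in r$outputs) {
      lines <- c(lines, paste(rid, "->", canonical_name(s)))
    }
  }
  lines <- unique(lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @export
print.crn <- function(x, ...) {
  cat("Chemical reaction network: ", n_species(x), " species, ",
      n_reactions(x), " reactions\n", sep = "")
  for (l in write_crn_text(x)) cat(l, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a CRN into a one-row-per-reaction tibble
#'
#' @param x A `crn` object.
#' @param ... Unused.
#' @return A tibble with columns `reaction` (id), `inputs`, `outputs`
#'   (display strings), `propensity` (kind) and `rate` (the mass-action rate
#'   constant, or `k` for Hill propensities; `NA` for general expressions).
#' @method tidy crn
#' @export
tidy.crn <- function(x, ...) {
  n <- n_reactions(x)
  tibble::tibble(
    reaction = if (n) paste0("r", seq_len(n)) else character(),
    inputs = vapply(x$reactions, function(r) side_display(r$inputs),
                    character(1)),
    outputs = vapply(x$reactions, function(r) side_display(r$outputs),
                     character(1)),
    propensity = vapply(x$reactions, function(r) r$propensity$kind,
                        character(1)),
    rate = vapply(x$reactions, function(r) {
      k <- r$propensity$parameters["k"]
      if (is.null(k) || is.na(k)) NA_real_ else as.numeric(k)
    }, numeric(1))
  )
}

#' One-row summary of a CRN
#'
#' @param x A `crn` object.
#' @param ... Unused.
#' @return A tibble with `n_species`, `n_reactions` and the number of
#'   reactions per propensity kind.
#' @method glance crn
#' @export
glance.crn <- function(x, ...) {
  kinds <- vapply(x$reactions, function(r) r$propensity$kind, character(1))
  tibble::tibble(
    n_species = n_species(x),
    n_reactions = n_reactions(x),
    n_massaction = sum(kinds == "massaction"),
    n_hill = sum(kinds %in% c("hill_positive", "hill_negative")),
    n_general = sum(kinds == "general")
  )
}

#' Species of a CRN as a tibble
#' @param crn A `crn` object.
#' @return A tibble with `canonical`, `display`, `material`, `attributes`.
#' @export
species_table <- function(crn) {
  tibble::tibble(
    canonical = species_names(crn),
    display = vapply(crn$species, species_display, character(1)),
    material = vapply(crn$species, function(s) s$material, character(1)),
    attributes = vapply(crn$species, function(s)
      paste(s$attributes, collapse = ","), character(1))
  )
}
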