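#' Component enumerators
#'
#' Component enumeration generates new components dynamically during
#' compilation: an enumerator is a function \eqn{g: C \to C'} on component
#' sets with \eqn{C \subseteq C'}, applied repeatedly until no new
#' components appear or a recursion-depth cap is reached. Local enumerators
#' are stored on a component and see only that component; global enumerators
#' are stored on the mixture and see the whole component set.
#'
#' @param scope `"local"` or `"global"`.
#' @param fn Function taking a list of components and returning a list of
#'   components that contains its input (new components appended).
#' @param name Enumerator name (for logs).
#' @return A `component_enumerator` object.
#' @export
component_enumerator <- function(scope = c("local", "global"), fn,
                                 name = "enumerator") {
  scope <- match.arg(scope)
  stopifnot(is.function(fn))
  structure(list(scope = scope, fn = fn, name = name),
            class = "component_enumerator")
}

#' Run component enumeration to a fixed point
#'
#' Applies all global enumerators to the full component set and all local
#' enumerators to their owning components (including components created in
#' earlier rounds), round by round. Component identity is the component
#' name: two generated components with equal names are the same component,
#' which prevents infinite renaming loops. Iteration stops at a fixed point
#' (no new names) or at `max_depth` rounds; hitting the cap while the last
#' round still produced new components emits a warning, not an error.
#'
#' @param initial List of `crn_component`s.
#' @param enumerators List of global [component_enumerator]s.
#' @param max_depth Maximum number of rounds (>= 1).
#' @param include_local Whether to run the components' own local enumerators
#'   (`TRUE` by default; the compiler runs a global-only phase first, then a
#'   local-only phase).
#' @return A list of components containing `initial` as a prefix, in
#'   first-created order.
#' @export
enumerate_fixed_point <- function(initial, enumerators = list(),
                                  max_depth = 8L, include_local = TRUE) {
  if (!is.numeric(max_depth) || max_depth < 1) {
    stop("max_depth must be >= 1", call. = FALSE)
  }
  max_depth <- as.integer(max_depth)
  current <- initial
  known <- vapply(current, `[[`, character(1), "name")
  if (anyDuplicated(known)) {
    stop("component names must be unique; duplicated: ",
         paste(unique(known[duplicated(known)]), collapse = ", "),
         call. = FALSE)
  }
  capped <- TRUE
  for (round in seq_len(max_depth)) {
    produced <- list()
    for (g in enumerators) {
      if (g$scope == "global") produced <- c(produced, g$fn(current))
    }
    if (include_local) {
      for (comp in current) {
        for (e in comp$local_enumerators) {
          if (e$scope == "local") produced <- c(produced, e$fn(list(comp)))
        }
      }
    }
    added <- FALSE
    for (p in produced) {
      stopifnot(inherits(p, "crn_component"))
      if (!p$name %in% known) {
        current[[length(current) + 1L]] <- p
        known <- c(known, p$name)
        added <- TRUE
      }
    }
    if (!added) { capped <- FALSE; break }
  }
  if (capped && max_depth > 0L) {
    warning("component enumeration stopped at depth cap ", max_depth,
            " before reaching a fixed point", call. = FALSE)
  }
  current
}

# ---- DNA constructs and transcript inference -------------------------------

PART_TYPES <- c("promoter", "rbs", "cds", "terminator")

#' DNA construct component
#'
#' An annotated piece of DNA given as an ordered list of oriented parts
#' (promoters, RBSs, coding sequences, terminators) on a linear or circular
#' backbone. During compilation a local component enumerator scans the part
#' list and infers every transcript (see [transcript_enumeration()]); each
#' inferred transcript becomes an [rna_construct()] component, and the DNA
#' construct itself emits one transcription reaction per transcript through
#' the resolved transcription mechanism.
#'
#' Parts can be given as a data frame with columns `name`, `part_type`,
#' `orientation`, or as a compact string `"name:type:orientation"`
#' comma-separated, with orientation `forward`/`reverse` (abbreviations
#' `fwd`/`rev` accepted), e.g.
#' `"prom:promoter:forward,rbs1:rbs:forward,gfp:cds:forward,t1:terminator:forward"`.
#'
#' @param name Construct name.
#' @param parts Part specification (non-empty).
#' @param topology `"linear"` or `"circular"`.
#' @inheritParams dna_assembly
#' @return A `crn_dna_construct` component.
#' @export
dna_construct <- function(name, parts, topology = c("linear", "circular"),
                          mechanisms = list(), parameters = NULL,
                          enumerators = list()) {
  topology <- match.arg(topology)
  parts <- normalize_parts(parts)
  if (nrow(parts) == 0L) {
    stop("a DNA construct needs at least one part", call. = FALSE)
  }
  enum <- component_enumerator("local", construct_local_enumerator,
                               name = "transcript_enumeration")
  crn_component(name, "dna_construct", mechanisms = mechanisms,
                parameters = parameters,
                enumerators = c(enumerators, list(enum)),
                parts = parts, topology = topology)
}

normalize_parts <- function(parts) {
  if (is.character(parts) && length(parts) == 1L) {
    parts <- parse_construct_string(parts)
  }
  if (!is.data.frame(parts)) {
    stop("parts must be a data frame or a construct string", call. = FALSE)
  }
  need <- c("name", "part_type", "orientation")
  if (!all(need %in% names(parts))) {
    stop("parts need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    name = as.character(parts$name),
    part_type = as.character(parts$part_type),
    orientation = normalize_orientation(as.character(parts$orientation))
  )
  for (nm in out$name) check_token(nm, "part name")
  bad <- setdiff(out$part_type, PART_TYPES)
  if (length(bad)) {
    stop("unknown part types: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  out
}

normalize_orientation <- function(x) {
  x <- tolower(x)
  x[x %in% c("fwd", "f", "+")] <- "forward"
  x[x %in% c("rev", "r", "-")] <- "reverse"
  bad <- setdiff(x, c("forward", "reverse"))
  if (length(bad)) {
    stop("unknown orientations: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  x
}

#' @rdname dna_construct
#' @param text A `"name:type:orientation"` comma-separated part string.
#' @export
parse_construct_string <- function(text) {
  tokens <- trimws(strsplit(text, ",", fixed = TRUE)[[1L]])
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    stop("empty construct string", call. = FALSE)
  }
  fields <- strsplit(tokens, ":", fixed = TRUE)
  bad <- vapply(fields, function(f) length(f) != 3L, logical(1))
  if (any(bad)) {
    stop("malformed part token(s): ",
         paste(tokens[bad], collapse = ", "),
         " (expected name:type:orientation)", call. = FALSE)
  }
  tibble::tibble(
    name = vapply(fields, `[[`, character(1), 1L),
    part_type = vapply(fields, `[[`, character(1), 2L),
    orientation = vapply(fields, `[[`, character(1), 3L)
  )
}

#' Reverse-complement a construct
#'
#' Reverses the part order and flips every orientation; the transcript set
#' of the reversed construct is the mirror image of the original's.
#'
#' @param construct A `crn_dna_construct`.
#' @return The reversed construct (name suffixed `"rc"`).
#' @export
reverse_construct <- function(construct) {
  parts <- construct$parts[rev(seq_len(nrow(construct$parts))), ]
  parts$orientation <- ifelse(parts$orientation == "forward",
                              "reverse", "forward")
  dna_construct(paste0(construct$name, "rc"), parts,
                topology = construct$topology,
                mechanisms = construct$local_mechanisms,
                parameters = construct$local_parameters)
}

#' Infer transcripts from a DNA construct
#'
#' For every forward-oriented promoter the scan walks rightward collecting
#' in-orientation RBS and CDS parts until the first forward-oriented
#' terminator (terminators are absolute: the first in-orientation terminator
#' always stops the scan). Reverse-oriented promoters scan leftward over
#' reverse-oriented parts symmetrically; collected parts are reported in
#' transcript (promoter-proximal first) order. On a circular construct the
#' scan wraps at most one full revolution. A promoter with no in-orientation
#' terminator yields a run-off transcript to the construct end (linear) or a
#' full-circle transcript (circular); run-offs are flagged in the result.
#'
#' @param construct A `crn_dna_construct`.
#' @return A list of transcript records: `name` (construct name + `"tx"` +
#'   promoter position), `promoter`, `promoter_index`, `orientation`,
#'   `terminator` (`NA` for run-offs), `parts` (tibble of collected rbs/cds
#'   parts in transcript order) and `runoff`.
#' @export
transcript_enumeration <- function(construct) {
  stopifnot(inherits(construct, "crn_dna_construct"))
  parts <- construct$parts
  n <- nrow(parts)
  circular <- construct$topology == "circular"
  out <- list()
  for (i in seq_len(n)) {
    if (parts$part_type[i] != "promoter") next
    orient <- parts$orientation[i]
    step <- if (orient == "forward") 1L else -1L
    idx <- integer()
    j <- i
    for (k in seq_len(n - 1L)) {
      j <- j + step
      if (j > n) { if (circular) j <- 1L else break }
      if (j < 1L) { if (circular) j <- n else break }
      idx <- c(idx, j)
    }
    collected <- integer()
    terminator <- NA_character_
    for (j in idx) {
      if (parts$orientation[j] != orient) next
      if (parts$part_type[j] == "terminator") {
        terminator <- parts$name[j]
        break
      }
      if (parts$part_type[j] %in% c("rbs", "cds")) {
        collected <- c(collected, j)
      }
    }
    out[[length(out) + 1L]] <- list(
      name = paste0(construct$name, "tx", i),
      promoter = parts$name[i],
      promoter_index = i,
      orientation = orient,
      terminator = terminator,
      parts = parts[collected, , drop = FALSE],
      runoff = is.na(terminator)
    )
  }
  out
}

#' RNA construct component
#'
#' The transcript-level component produced by scanning a DNA construct: it
#' carries the RBS/CDS parts between its promoter and terminator in
#' transcript order and contains no promoter or terminator parts. Its update
#' emits one translation (through the resolved translation mechanism) per
#' adjacent (RBS, CDS) pair in transcript order, producing one protein per
#' pair named after the CDS.
#'
#' @param name Component (and RNA species) name.
#' @param parts Tibble of rbs/cds parts in transcript order.
#' @inheritParams dna_assembly
#' @return A `crn_rna_construct` component.
#' @export
rna_construct <- function(name, parts, mechanisms = list(),
                          parameters = NULL) {
  parts <- normalize_parts(parts[, c("name", "part_type", "orientation")])
  if (any(parts$part_type %in% c("promoter", "terminator"))) {
    stop("an RNA construct may not contain promoter or terminator parts",
         call. = FALSE)
  }
  crn_component(name, "rna_construct", mechanisms = mechanisms,
                parameters = parameters, parts = parts)
}

# zero-row part tibbles are legal for rna_construct (a transcript with no
# functional parts still exists as a species)
construct_local_enumerator <- function(components) {
  out <- components
  for (comp in components) {
    if (!inherits(comp, "crn_dna_construct")) next
    for (tx in transcript_enumeration(comp)) {
      if (tx$runoff) {
        message("run-off transcript ", tx$name, " (promoter ", tx$promoter,
                " has no in-orientation terminator)")
      }
      out[[length(out) + 1L]] <-
        rna_construct(tx$name, tx$parts,
                      mechanisms = comp$local_mechanisms,
                      parameters = comp$local_parameters)
    }
  }
  out
}

#' @export
component_update.crn_dna_construct <- function(component, ctx) {
  dna <- crn_species(component$name, "dna")
  out <- mech_out(list(dna), list())
  for (tx in transcript_enumeration(component)) {
    mech <- resolve_mechanism(component, ctx$mechanisms, "transcription",
                              ctx = ctx)
    params <- resolve_mech_params(component, ctx$parameters, mech,
                                  extra_part_ids = tx$promoter, ctx = ctx)
    upd <- mech$update(mech, list(dna = dna,
                                  transcript = crn_species(tx$name, "rna"),
                                  regulator = component$regulator), params)
    out <- combine_updates(out, upd)
  }
  out
}

#' @export
component_update.crn_rna_construct <- function(component, ctx) {
  rna <- crn_species(component$name, "rna")
  out <- mech_out(list(rna), list())
  parts <- component$parts
  if (nrow(parts) >= 2L) {
    for (i in seq_len(nrow(parts) - 1L)) {
      if (parts$part_type[i] == "rbs" && parts$part_type[i + 1L] == "cds") {
        mech <- resolve_mechanism(component, ctx$mechanisms, "translation",
                                  ctx = ctx)
        params <- resolve_mech_params(component, ctx$parameters, mech,
                                      extra_part_ids = parts$name[i],
                                      ctx = ctx)
        protein <- crn_species(parts$name[i + 1L], "protein")
        upd <- mech$update(mech, list(rna = rna, protein = protein), params)
        out <- combine_updates(out, upd)
      }
    }
  }
  out
}
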