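#' Create a reaction
#'
#' A reaction transforms an input multiset of species into an output multiset
#' at a rate given by its propensity. Multisets are written as lists with
#' repetition (`list(A, A)` means `2A`). Inputs and outputs may individually
#' be empty (production from, or degradation to, nothing) but not both.
#'
#' @param inputs,outputs Lists of `crn_species` (repetition = multiplicity).
#' @param propensity A `crn_propensity`, or a single number as shorthand for
#'   [massaction()] with that rate constant.
#' @return A `crn_reaction` object.
#' @examples
#' A <- crn_species("A"); B <- crn_species("B")
#' crn_reaction(list(A), list(B), 0.5)
#' @export
crn_reaction <- function(inputs, outputs, propensity) {
  if (is.numeric(propensity)) propensity <- massaction(propensity)
  stopifnot(inherits(propensity, "crn_propensity"))
  inputs <- normalize_multiset(inputs, "inputs")
  outputs <- normalize_multiset(outputs, "outputs")
  if (length(inputs) == 0L && length(outputs) == 0L) {
    stop("a reaction cannot have both empty inputs and empty outputs",
         call. = FALSE)
  }
  structure(list(inputs = inputs, outputs = outputs, propensity = propensity),
            class = "crn_reaction")
}

normalize_multiset <- function(x, what) {
  if (is.null(x)) return(list())
  if (inherits(x, "crn_species")) x <- list(x)
  if (!is.list(x)) stop(what, " must be a list of species", call. = FALSE)
  for (s in x) {
    if (!inherits(s, "crn_species")) {
      stop("all ", what, " must be crn_species objects", call. = FALSE)
    }
  }
  x
}

# identity string: same inputs, outputs, propensity kind and parameters
# => same reaction. Input/output multisets are order-insensitive.
reaction_serial <- function(r) {
  side <- function(sl) {
    tab <- stoich_table(sl)
    if (length(tab) == 0L) return("0")
    paste(sort_c(paste0(as.integer(tab), "*", names(tab))), collapse = "+")
  }
  paste0(side(r$inputs), "=>", side(r$outputs), "@",
         propensity_serial(r$propensity))
}

# all species a reaction touches (inputs, outputs, propensity roles),
# first-encountered order
reaction_species <- function(r) {
  c(r$inputs, r$outputs, propensity_species(r$propensity))
}

#' Build a reversible reaction as two irreversible reactions
#'
#' All reversible processes (written with a double arrow in the literature)
#' are stored as a forward/reverse pair of irreversible mass-action
#' reactions, which keeps propensity handling uniform and matches how the
#' reactions are exported to SBML (`reversible="false"` throughout).
#' Zero rates are retained, not pruned, so the compiled network structure
#' never depends on parameter values.
#'
#' @param inputs,outputs Lists of species (the left and right side).
#' @param kf,kr Forward and reverse mass-action rate constants.
#' @return A list of two `crn_reaction`s: forward then reverse.
#' @examples
#' G <- crn_species("X", "dna"); P <- crn_species("P")
#' reversible_pair(list(G, P), list(crn_complex(list(G, P))), 100, 10)
#' @export
reversible_pair <- function(inputs, outputs, kf, kr) {
  check_rate(kf, "kf"); check_rate(kr, "kr")
  list(crn_reaction(inputs, outputs, massaction(kf)),
       crn_reaction(outputs, inputs, massaction(kr)))
}

side_display <- function(sl) {
  tab <- stoich_table(sl)
  if (length(tab) == 0L) return("0")
  sp <- attr(tab, "species")
  paste(vapply(seq_along(tab), function(i) {
    d <- species_display(sp[[i]])
    if (tab[[i]] > 1L) paste0(tab[[i]], " ", d) else d
  }, character(1)), collapse = " + ")
}

arrow_display <- function(p) {
  switch(
    p$kind,
    massaction = paste0("--", fmt_num(p$parameters[["k"]]), "-->"),
    hill_positive = ,
    hill_negative = {
      bits <- paste0(c("k", "K", "n"), "=",
                     fmt_num(p$parameters[c("k", "K", "n")]), collapse = ",")
      extra <- paste0(",r=", species_display(p$regulator))
      if (!is.null(p$scaling)) {
        extra <- paste0(extra, ",d=", species_display(p$scaling))
      }
      paste0("--", p$kind, "(", bits, extra, ")-->")
    },
    general = paste0("--general[", p$expression, "]-->")
  )
}

#' Format a reaction as a one-line string
#'
#' Mass-action reactions print as `A + B --k--> C`; Hill and general
#' propensities spell out their kind and parameters in the arrow.
#'
#' @param r A `crn_reaction`.
#' @return A single string.
#' @export
reaction_display <- function(r) {
  paste(side_display(r$inputs), arrow_display(r$propensity),
        side_display(r$outputs))
}

#' @export
print.crn_reaction <- function(x, ...) {
  cat(reaction_display(x), "\n")
  invisible(x)
}

#' @export
format.crn_reaction <- function(x, ...) reaction_display(x)
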