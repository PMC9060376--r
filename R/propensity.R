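# Deterministic number formatting used everywhere a rate constant is printed
# or serialized (pretty-printer, reaction identity, SBML). 15 significant
# digits round-trips doubles in practice while keeping output readable.
fmt_num <- function(x) formatC(x, format = "g", digits = 15, width = 1)

check_rate <- function(x, what, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(what, " must be a single finite number", call. = FALSE)
  }
  if (positive && x <= 0) stop(what, " must be > 0", call. = FALSE)
  if (!positive && x < 0) stop(what, " must be >= 0", call. = FALSE)
  as.numeric(x)
}

#' Propensity (rate-law) constructors
#'
#' A propensity is the rate function \eqn{\rho(s;\theta)} attached to a
#' reaction. Four kinds are supported:
#' \describe{
#'   \item{mass action}{\eqn{k \prod_i s_i^{n_i}} over the reaction's input
#'     multiplicities \eqn{n_i}, using the deterministic concentration
#'     convention (\eqn{s^2} for a doubled input, not \eqn{s(s-1)}).}
#'   \item{positive Hill}{\eqn{k\, d\, r^n / (K^n + r^n)} in a regulator
#'     species \eqn{r}, optionally scaled by a species \eqn{d} (e.g. the
#'     gene copy concentration); \eqn{d \equiv 1} when unset.}
#'   \item{negative Hill}{\eqn{k\, d\, K^n / (K^n + r^n)}.}
#'   \item{general}{an arithmetic expression over species canonical names
#'     (or bare names of untyped species) and named constants.}
#' }
#'
#' @param k Rate constant (finite, non-negative).
#' @param K Hill half-max constant, must be > 0.
#' @param n Hill coefficient, must be > 0.
#' @param regulator The regulator species \eqn{r} (a `crn_species`).
#' @param scaling Optional scaling species \eqn{d}, or `NULL`.
#' @param expression A string with an arithmetic expression (`+ - * / ^` and
#'   parentheses).
#' @param constants Named numeric vector of constants the expression uses.
#' @return An object of class `crn_propensity`.
#' @examples
#' massaction(0.1)
#' hill_negative(k = 1, K = 20, n = 2, regulator = crn_species("B", "protein"))
#' @name propensity
NULL

new_propensity <- function(kind, parameters, regulator = NULL, scaling = NULL,
                           expression = NULL) {
  structure(
    list(kind = kind, parameters = parameters, regulator = regulator,
         scaling = scaling, expression = expression),
    class = "crn_propensity"
  )
}

#' @rdname propensity
#' @export
massaction <- function(k) {
  new_propensity("massaction", c(k = check_rate(k, "k")))
}

hill_propensity <- function(kind, k, K, n, regulator, scaling = NULL) {
  stopifnot(inherits(regulator, "crn_species"))
  if (!is.null(scaling)) stopifnot(inherits(scaling, "crn_species"))
  new_propensity(
    kind,
    c(k = check_rate(k, "k"), K = check_rate(K, "K", positive = TRUE),
      n = check_rate(n, "n", positive = TRUE)),
    regulator = regulator, scaling = scaling
  )
}

#' @rdname propensity
#' @export
hill_positive <- function(k, K, n, regulator, scaling = NULL) {
  hill_propensity("hill_positive", k, K, n, regulator, scaling)
}

#' @rdname propensity
#' @export
hill_negative <- function(k, K, n, regulator, scaling = NULL) {
  hill_propensity("hill_negative", k, K, n, regulator, scaling)
}

#' @rdname propensity
#' @export
general_propensity <- function(expression, constants = numeric()) {
  if (!is.character(expression) || length(expression) != 1L ||
      !nzchar(expression)) {
    stop("expression must be a non-empty string", call. = FALSE)
  }
  if (length(constants) > 0 &&
      (is.null(names(constants)) || any(!nzchar(names(constants))))) {
    stop("constants must be a named numeric vector", call. = FALSE)
  }
  constants <- vapply(constants, check_rate, numeric(1), what = "constant")
  # parse now so malformed expressions fail at construction time
  expr <- tryCatch(str2lang(expression),
                   error = function(e) stop("cannot parse expression: ",
                                            conditionMessage(e), call. = FALSE))
  check_expr_ops(expr)
  new_propensity("general", constants, expression = expression)
}

# whitelist of callables inside a general-propensity expression
ALLOWED_EXPR_FUNS <- c("+", "-", "*", "/", "^", "(", "exp", "log", "sqrt",
                       "min", "max", "abs")

check_expr_ops <- function(e) {
  if (is.call(e)) {
    fn <- as.character(e[[1L]])
    if (!fn %in% ALLOWED_EXPR_FUNS) {
      stop("function ", sQuote(fn), " not allowed in propensity expressions",
           call. = FALSE)
    }
    for (i in seq_along(e)[-1L]) check_expr_ops(e[[i]])
  } else if (!(is.name(e) || is.numeric(e))) {
    stop("invalid token in propensity expression", call. = FALSE)
  }
  invisible(TRUE)
}

# species referenced by a propensity beyond the reaction inputs
propensity_species <- function(p) {
  out <- list()
  if (!is.null(p$regulator)) out <- c(out, list(p$regulator))
  if (!is.null(p$scaling)) out <- c(out, list(p$scaling))
  out
}

# stable serialization used for reaction identity and determinism checks
propensity_serial <- function(p) {
  pars <- p$parameters
  pars <- pars[sort_c(names(pars))]
  bits <- paste0(names(pars), "=", fmt_num(pars), collapse = ",")
  extra <- c(
    if (!is.null(p$regulator)) paste0("r=", canonical_name(p$regulator)),
    if (!is.null(p$scaling)) paste0("d=", canonical_name(p$scaling)),
    if (!is.null(p$expression)) paste0("expr=", p$expression)
  )
  paste(c(p$kind, bits, extra), collapse = ";")
}

# Build the state lookup for evaluation: canonical names, plus bare names of
# simple species when unambiguous.
state_value <- function(state, sp) {
  key <- canonical_name(sp)
  v <- state[[key]]
  if (is.null(v) && !is_complex(sp)) v <- state[[sp$name]]
  if (is.null(v) || is.na(v)) {
    stop("state has no value for species ", sQuote(species_display(sp)),
         call. = FALSE)
  }
  if (v < 0) {
    stop("negative state value for species ", sQuote(species_display(sp)),
         call. = FALSE)
  }
  v
}

#' Evaluate a propensity at a state
#'
#' @param p A `crn_propensity`.
#' @param inputs List of input species (the reaction's input multiset; used
#'   by mass-action kinetics).
#' @param state Named numeric vector or list of non-negative concentrations,
#'   keyed by canonical species name (bare names work for untyped species).
#' @return The non-negative, finite rate value.
#' @examples
#' A <- crn_species("A"); B <- crn_species("B")
#' evaluate_propensity(massaction(2), list(A, B), c(A = 3, B = 4))  # 24
#' @export
evaluate_propensity <- function(p, inputs = list(), state = numeric()) {
  stopifnot(inherits(p, "crn_propensity"))
  state <- as.list(state)
  bad <- vapply(state, function(v) !is.numeric(v) || !is.finite(v) || v < 0,
                logical(1))
  if (any(bad)) {
    stop("state values must be finite and non-negative; offending: ",
         paste(names(state)[bad], collapse = ", "), call. = FALSE)
  }
  val <- switch(
    p$kind,
    massaction = {
      k <- p$parameters[["k"]]
      if (length(inputs) == 0) k
      else {
        tab <- stoich_table(inputs)
        conc <- vapply(attr(tab, "species"), state_value, numeric(1),
                       state = state)
        k * prod(conc^as.numeric(tab))
      }
    },
    hill_positive = ,
    hill_negative = {
      k <- p$parameters[["k"]]; K <- p$parameters[["K"]]
      n <- p$parameters[["n"]]
      r <- state_value(state, p$regulator)
      d <- if (is.null(p$scaling)) 1 else state_value(state, p$scaling)
      num <- if (p$kind == "hill_positive") r^n else K^n
      k * d * num / (K^n + r^n)
    },
    general = {
      env <- new.env(parent = baseenv())
      for (nm in names(p$parameters)) assign(nm, p$parameters[[nm]], env)
      for (nm in names(state)) {
        if (nzchar(nm)) assign(nm, state[[nm]], env)
      }
      v <- tryCatch(eval(str2lang(p$expression), env),
                    error = function(e) stop("propensity expression failed: ",
                                             conditionMessage(e),
                                             call. = FALSE))
      v
    },
    stop("unknown propensity kind ", p$kind, call. = FALSE)
  )
  if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val < 0) {
    stop("propensity evaluated to a non-finite or negative value",
         call. = FALSE)
  }
  as.numeric(val)
}

#' @export
print.crn_propensity <- function(x, ...) {
  cat(propensity_serial(x), "\n")
  invisible(x)
}

# multiset -> stoichiometry; returns named integer vector (canonical name ->
# multiplicity, first-encountered order) with the distinct species attached.
stoich_table <- function(species_list) {
  keys <- vapply(species_list, canonical_name, character(1))
  uk <- unique(keys)
  counts <- vapply(uk, function(k) sum(keys == k), integer(1))
  sp <- species_list[match(uk, keys)]
  structure(counts, names = uk, species = sp)
}
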