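#' Parameter databases with hierarchical defaulting
#'
#' Compilation resolves every rate constant through a parameter database
#' keyed by `(mechanism, part_id, name)` triples, where `mechanism` and
#' `part_id` may be unspecified. Lookups search from most specific to least
#' specific key, so a sparse set of "ball-park" defaults can drive a full
#' compilation and be refined later with part- or mechanism-specific values.
#'
#' A database can be built from a named numeric vector (global defaults: both
#' `mechanism` and `part_id` unspecified) or from a data frame with columns
#' `mechanism`, `part_id`, `name`, `value` (NA or "" meaning unspecified).
#'
#' @param x Named numeric vector, data frame, or `NULL` for an empty
#'   database.
#' @param provenance Free-text origin recorded on each entry (used in audit
#'   logs).
#' @return A `parameter_db` object (a tibble of entries).
#' @examples
#' parameter_db(c(kb = 100, ku = 10, ktx = 0.1, ktl = 0.5))
#' @export
parameter_db <- function(x = NULL, provenance = "inline") {
  if (is.null(x)) {
    df <- tibble::tibble(mechanism = character(), part_id = character(),
                         name = character(), value = numeric(),
                         provenance = character())
    return(structure(df, class = c("parameter_db", class(df))))
  }
  if (is.numeric(x)) {
    if (length(x) > 0 && (is.null(names(x)) || any(!nzchar(names(x))))) {
      stop("numeric parameter sets must be fully named", call. = FALSE)
    }
    df <- tibble::tibble(mechanism = NA_character_, part_id = NA_character_,
                         name = names(x), value = as.numeric(x),
                         provenance = provenance)
    return(db_from_rows(df))
  }
  if (is.data.frame(x)) {
    need <- c("mechanism", "part_id", "name", "value")
    miss <- setdiff(need, names(x))
    if (length(miss)) {
      stop("parameter data frame lacks columns: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    df <- tibble::tibble(
      mechanism = blank_to_na(as.character(x$mechanism)),
      part_id = blank_to_na(as.character(x$part_id)),
      name = as.character(x$name),
      value = as.numeric(x$value),
      provenance = if ("provenance" %in% names(x))
        as.character(x$provenance) else provenance
    )
    return(db_from_rows(df))
  }
  stop("cannot build a parameter_db from ", class(x)[1], call. = FALSE)
}

blank_to_na <- function(x) {
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  trimws(x)
}

key_string <- function(mechanism, part_id, name) {
  paste0("(", ifelse(is.na(mechanism), "", mechanism), ", ",
         ifelse(is.na(part_id), "", part_id), ", ", name, ")")
}

# dedupe on (mechanism, part_id, name): later rows win, with a warning
db_from_rows <- function(df) {
  if (any(is.na(df$name) | !nzchar(df$name))) {
    stop("parameter name must be non-empty in every row", call. = FALSE)
  }
  if (any(!is.finite(df$value))) {
    stop("parameter values must be finite numbers", call. = FALSE)
  }
  key <- paste(ifelse(is.na(df$mechanism), "\r", df$mechanism),
               ifelse(is.na(df$part_id), "\r", df$part_id), df$name,
               sep = "\n")
  dup <- duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    for (i in which(dup)) {
      warning("duplicate parameter key ",
              key_string(df$mechanism[i], df$part_id[i], df$name[i]),
              ": later value overrides", call. = FALSE)
    }
    df <- df[!dup, , drop = FALSE]
  }
  structure(df, class = c("parameter_db", class(tibble::tibble())))
}

#' Merge parameter databases
#'
#' Entries from later databases override identical keys in earlier ones
#' (with a warning).
#'
#' @param ... `parameter_db` objects.
#' @return A `parameter_db`.
#' @export
merge_parameter_db <- function(...) {
  dbs <- list(...)
  rows <- do.call(rbind, lapply(dbs, function(d) as.data.frame(d)))
  db_from_rows(tibble::as_tibble(rows))
}

#' Look up a parameter through the defaulting hierarchy
#'
#' The search runs from most-specific to least-specific key:
#' \enumerate{
#'   \item `(mechanism_name, part_id, name)`
#'   \item `(mechanism_type, part_id, name)`
#'   \item `(unspecified, part_id, name)`
#'   \item `(mechanism_name, unspecified, name)`
#'   \item `(mechanism_type, unspecified, name)`
#'   \item `(unspecified, unspecified, name)`
#' }
#' Part-specific entries beat mechanism-specific entries, which beat global
#' defaults. When `part_id` has several candidates (e.g. a component name and
#' a sub-part name), the part tiers (1–3) are tried for each candidate in
#' order before falling back to the part-free tiers (4–6). The matched key is
#' returned so callers can log which value was defaulted.
#'
#' @param db A `parameter_db`.
#' @param mechanism_name,mechanism_type Optional mechanism instance name and
#'   mechanism type strings (`NULL` to skip those tiers).
#' @param part_id Optional component/part identifier; may be a character
#'   vector of candidates in priority order.
#' @param name Required parameter name (e.g. `"ktx"`, `"kb"`).
#' @return A list with `value`, `key` (list: mechanism, part_id, name),
#'   `tier` (1–6) and `provenance`; or an error naming every attempted key.
#' @examples
#' db <- parameter_db(c(kb = 100))
#' find_parameter(db, part_id = "prom1", name = "kb")$value
#' @export
find_parameter <- function(db, mechanism_name = NULL, mechanism_type = NULL,
                           part_id = NULL, name) {
  stopifnot(inherits(db, "parameter_db"))
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("parameter name must be a non-empty string", call. = FALSE)
  }
  norm <- function(x) {
    if (is.null(x) || length(x) == 0) return(character())
    x <- as.character(x)
    x[!is.na(x) & nzchar(x)]
  }
  mech_name <- norm(mechanism_name)[1]
  mech_type <- norm(mechanism_type)[1]
  parts <- norm(part_id)

  # candidate keys (mech, part, tier) in search order
  cand <- list()
  push <- function(m, p, tier) {
    cand[[length(cand) + 1L]] <<- list(mechanism = m, part_id = p,
                                       tier = tier)
  }
  for (p in parts) {
    if (!is.na(mech_name)) push(mech_name, p, 1L)
    if (!is.na(mech_type)) push(mech_type, p, 2L)
    push(NA_character_, p, 3L)
  }
  if (!is.na(mech_name)) push(mech_name, NA_character_, 4L)
  if (!is.na(mech_type)) push(mech_type, NA_character_, 5L)
  push(NA_character_, NA_character_, 6L)

  for (k in cand) {
    hit <- which(
      (if (is.na(k$mechanism)) is.na(db$mechanism)
       else !is.na(db$mechanism) & db$mechanism == k$mechanism) &
      (if (is.na(k$part_id)) is.na(db$part_id)
       else !is.na(db$part_id) & db$part_id == k$part_id) &
      db$name == name
    )
    if (length(hit)) {
      i <- hit[[1L]]
      return(list(
        value = db$value[i],
        key = list(mechanism = db$mechanism[i], part_id = db$part_id[i],
                   name = name),
        tier = k$tier,
        provenance = db$provenance[i]
      ))
    }
  }
  attempted <- vapply(cand, function(k)
    key_string(k$mechanism, k$part_id, name), character(1))
  stop("no parameter found for ", sQuote(name), "; attempted keys in order: ",
       paste(attempted, collapse = " -> "), call. = FALSE)
}

#' Read a parameter file
#'
#' Parameter files are UTF-8 delimited text (tab or comma, auto-detected from
#' the header line) with required header columns `mechanism`, `part_id`,
#' `param_name`, `value`. Blank cells mean "unspecified"; lines starting with
#' `#` are ignored. Later rows override earlier rows with the same key (a
#' warning is emitted per override).
#'
#' @param path File path.
#' @param dialect `"auto"` (default), `"tab"` or `"comma"`.
#' @return A `parameter_db`.
#' @export
load_parameter_file <- function(path, dialect = c("auto", "tab", "comma")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("parameter file not found: ", path, call. = FALSE)
  }
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    stop("parameter file ", path, " has no header line", call. = FALSE)
  }
  sep <- switch(dialect, tab = "\t", comma = ",",
                auto = if (grepl("\t", lines[[1L]])) "\t" else ",")
  cells <- strsplit(lines, sep, fixed = TRUE)
  header <- trimws(cells[[1L]])
  need <- c("mechanism", "part_id", "param_name", "value")
  if (!all(need %in% header)) {
    stop("parameter file ", path, " must have header columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  idx <- match(need, header)
  rows <- lapply(seq_along(cells)[-1L], function(i) {
    row <- trimws(cells[[i]])
    if (length(row) < max(idx)) {
      stop("malformed row at line ", lineno[i], " of ", path,
           ": expected at least ", max(idx), " fields", call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(row[idx[4L]]))
    if (is.na(v)) {
      stop("non-numeric value ", sQuote(row[idx[4L]]), " at line ",
           lineno[i], " of ", path, call. = FALSE)
    }
    tibble::tibble(mechanism = row[idx[1L]], part_id = row[idx[2L]],
                   name = row[idx[3L]], value = v,
                   provenance = paste0(basename(path), ":", lineno[i]))
  })
  if (length(rows) == 0L) return(parameter_db())
  df <- do.call(rbind, rows)
  df$mechanism <- blank_to_na(df$mechanism)
  df$part_id <- blank_to_na(df$part_id)
  db_from_rows(df)
}

#' Write a parameter database to a delimited file
#'
#' Inverse of [load_parameter_file()]: the written file loads back to the
#' same entry set.
#'
#' @param db A `parameter_db`.
#' @param path Output path.
#' @param sep Field separator, tab by default.
#' @return `path`, invisibly.
#' @export
write_parameter_file <- function(db, path, sep = "\t") {
  stopifnot(inherits(db, "parameter_db"))
  na_blank <- function(x) ifelse(is.na(x), "", x)
  lines <- c(
    paste(c("mechanism", "part_id", "param_name", "value"), collapse = sep),
    vapply(seq_len(nrow(db)), function(i) {
      paste(c(na_blank(db$mechanism[i]), na_blank(db$part_id[i]),
              db$name[i], fmt_num(db$value[i])), collapse = sep)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
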