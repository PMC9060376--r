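# Independent oracles used by the property suites. These deliberately avoid
# the package's own scan/closure implementations: the transcript oracle
# works on index vectors, the closure oracle on name sets.

# Brute-force transcript oracle: for every promoter, list the downstream
# positions in scan order, pick the first in-orientation terminator among
# them, and keep the in-orientation rbs/cds parts before it.
oracle_transcripts <- function(parts, topology) {
  n <- nrow(parts)
  out <- list()
  for (p in seq_len(n)) {
    if (parts$part_type[p] != "promoter") next
    o <- parts$orientation[p]
    step <- if (o == "forward") 1L else -1L
    downstream <- ((p - 1L + step * seq_len(n - 1L)) %% n) + 1L
    if (topology == "linear") {
      n_keep <- if (o == "forward") n - p else p - 1L
      downstream <- downstream[seq_len(n_keep)]
    }
    in_orient <- downstream[parts$orientation[downstream] == o]
    terms <- in_orient[parts$part_type[in_orient] == "terminator"]
    stop_at <- if (length(terms)) {
      match(terms[[1L]], downstream) - 1L
    } else {
      length(downstream)
    }
    region <- downstream[seq_len(stop_at)]
    keep <- region[parts$orientation[region] == o &
                     parts$part_type[region] %in% c("rbs", "cds")]
    out[[length(out) + 1L]] <- list(
      promoter_index = p,
      terminator = if (length(terms)) parts$name[terms[[1L]]]
                   else NA_character_,
      parts = parts$name[keep]
    )
  }
  out
}

# canonical comparable form of a transcript set: sorted strings
# "promoterindex|terminator|part,part,..."
transcript_triples <- function(txs) {
  sort(vapply(txs, function(t) {
    paste(t$promoter_index, ifelse(is.na(t$terminator), "-", t$terminator),
          paste(t$parts$name, collapse = ","), sep = "|")
  }, character(1)))
}

oracle_triples <- function(oracle) {
  sort(vapply(oracle, function(t) {
    paste(t$promoter_index, ifelse(is.na(t$terminator), "-", t$terminator),
          paste(t$parts, collapse = ","), sep = "|")
  }, character(1)))
}

# Toy global enumerator: for every unordered pair of distinct components,
# add a component named by the concatenation of the sorted pair names.
dimer_name <- function(a, b) paste(sort(c(a, b)), collapse = "")

dimerizer_enumerator <- function(only_letters = FALSE) {
  component_enumerator("global", function(components) {
    out <- components
    nms <- vapply(components, `[[`, character(1), "name")
    for (i in seq_along(nms)) {
      for (j in seq_along(nms)) {
        if (i >= j) next
        if (only_letters && (nchar(nms[i]) > 1L || nchar(nms[j]) > 1L)) next
        nm <- dimer_name(nms[i], nms[j])
        if (!nm %in% nms) out <- c(out, list(toy_component(nm)))
      }
    }
    out
  }, name = "dimerizer")
}

toy_component <- function(name) crn_component(name, "toy")

# Independent bounded closure over name sets, one round per depth unit.
oracle_dimer_closure <- function(init, rounds, only_letters = FALSE) {
  cur <- init
  for (r in seq_len(rounds)) {
    new <- character()
    for (i in seq_along(cur)) {
      for (j in seq_along(cur)) {
        if (i >= j) next
        if (only_letters && (nchar(cur[i]) > 1L || nchar(cur[j]) > 1L)) next
        new <- c(new, dimer_name(cur[i], cur[j]))
      }
    }
    nxt <- union(cur, new)
    if (setequal(nxt, cur)) break
    cur <- nxt
  }
  cur
}

# random species / complex trees for the canonical-name injectivity check
random_species_tree <- function(depth = 2L) {
  names_pool <- c("A", "B", "Cx", "d1", "e.2", "f-3", "XDNA", "P")
  attr_pool <- c("degradable", "machinery", "tag1")
  mat_pool <- c("dna", "rna", "protein", "small_molecule", "none")
  rand_simple <- function() {
    crn_species(sample(names_pool, 1L), sample(mat_pool, 1L),
                attributes = sample(attr_pool,
                                    sample(0:2, 1L)))
  }
  build <- function(d) {
    if (d <= 0L || stats::runif(1) < 0.6) return(rand_simple())
    k <- sample(2:3, 1L)
    crn_complex(lapply(seq_len(k), function(i) build(d - 1L)),
                attributes = sample(attr_pool, sample(0:1, 1L)))
  }
  build(depth)
}

# net stoichiometry of one species across a reaction
net_stoich <- function(reaction, species) {
  key <- canonical_name(species)
  count <- function(side) {
    sum(vapply(side, canonical_name, character(1)) == key)
  }
  count(reaction$outputs) - count(reaction$inputs)
}

extdata <- function(...) {
  system.file("extdata", ..., package = "crnforge", mustWork = TRUE)
}
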