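test_that("no enumerators means an immediate fixed point", {
  comps <- list(toy_component("A"), toy_component("B"))
  expect_identical(enumerate_fixed_point(comps, list(), 5), comps)
  expect_error(enumerate_fixed_point(comps, list(), 0), ">= 1")
})

test_that("the dimerizer closure matches brute force at depths 1-3", {
  init <- list(toy_component("A"), toy_component("B"))
  for (d in 1:3) {
    got <- suppressWarnings(
      enumerate_fixed_point(init, list(dimerizer_enumerator()), d))
    names_got <- vapply(got, `[[`, character(1), "name")
    expect_setequal(names_got, oracle_dimer_closure(c("A", "B"), d))
    # the output always contains its input
    expect_identical(names_got[1:2], c("A", "B"))
  }
})

test_that("the depth-cap warning fires exactly when the cap binds", {
  init <- list(toy_component("A"), toy_component("B"))
  # unrestricted dimerizer: still growing at every depth here
  for (d in 1:3) {
    grew <- !setequal(oracle_dimer_closure(c("A", "B"), d),
                      oracle_dimer_closure(c("A", "B"), d - 1))
    expect_true(grew)
    expect_warning(
      enumerate_fixed_point(init, list(dimerizer_enumerator()), d),
      "depth cap")
  }
  # letters-only dimerizer reaches its finite closure, so no warning
  expect_silent(
    got <- enumerate_fixed_point(init,
                                 list(dimerizer_enumerator(TRUE)), 10))
  expect_setequal(vapply(got, `[[`, character(1), "name"),
                  c("A", "B", "AB"))
})

test_that("transcript scan handles the canonical layouts", {
  # forward promoter, rbs, cds, terminator
  lin <- dna_construct("c1",
                       "p1:promoter:forward,u1:rbs:forward,g1:cds:forward,t1:terminator:forward")
  txs <- transcript_enumeration(lin)
  expect_length(txs, 1)
  expect_identical(txs[[1]]$parts$name, c("u1", "g1"))
  expect_identical(txs[[1]]$terminator, "t1")
  expect_false(txs[[1]]$runoff)
  # no terminator: run-off to the construct end
  runoff <- dna_construct("c2",
                          "p1:promoter:forward,u1:rbs:forward,g1:cds:forward")
  txs2 <- transcript_enumeration(runoff)
  expect_true(txs2[[1]]$runoff)
  expect_identical(txs2[[1]]$parts$name, c("u1", "g1"))
  # two convergent transcription units on opposite strands
  both <- dna_construct(
    "c3",
    paste0("p1:promoter:forward,u1:rbs:forward,g1:cds:forward,",
           "t1:terminator:forward,g2:cds:reverse,u2:rbs:reverse,",
           "p2:promoter:reverse"))
  trip <- transcript_triples(transcript_enumeration(both))
  expect_identical(trip, oracle_triples(oracle_transcripts(both$parts,
                                                           "linear")))
  # reverse transcript collects promoter-proximal first: u2 then g2
  rev_tx <- transcript_enumeration(both)[[2]]
  expect_identical(rev_tx$parts$name, c("u2", "g2"))
  # circular constructs wrap exactly once
  circ <- dna_construct("c4",
                        "g1:cds:forward,t1:terminator:forward,p1:promoter:forward",
                        topology = "circular")
  txs4 <- transcript_enumeration(circ)
  expect_identical(txs4[[1]]$parts$name, "g1")
  expect_identical(txs4[[1]]$terminator, "t1")
})

test_that("transcript enumeration matches the oracle on random constructs", {
  for (seed in 1:500) {
    len <- 1 + (seed %% 12)
    rc <- random_construct(seed, n_parts = len)
    expect_identical(transcript_triples(transcript_enumeration(rc)),
                     oracle_triples(oracle_transcripts(rc$parts,
                                                       rc$topology)),
                     info = paste("seed", seed))
  }
})

test_that("reversing a construct mirrors its transcript set", {
  for (seed in c(2, 17, 101, 333)) {
    rc <- random_construct(seed, n_parts = 9)
    fwd <- transcript_enumeration(rc)
    rev <- transcript_enumeration(reverse_construct(rc))
    strip <- function(txs) {
      sort(vapply(txs, function(t)
        paste(t$promoter, ifelse(is.na(t$terminator), "-", t$terminator),
              paste(t$parts$name, collapse = ","), sep = "|"),
        character(1)))
    }
    expect_identical(strip(fwd), strip(rev))
  }
})

test_that("RNA constructs reject promoters and terminators", {
  expect_error(
    rna_construct("r1", tibble::tibble(name = "p1", part_type = "promoter",
                                       orientation = "forward")),
    "may not contain")
})

test_that("a DNA construct compiles transcription and translation end-to-end", {
  m <- crn_mixture(
    "cm",
    components = list(dna_construct(
      "plasmid",
      paste0("prom:promoter:forward,u1:rbs:forward,gfp:cds:forward,",
             "t1:terminator:forward,p2:promoter:forward,u2:rbs:forward,",
             "rfp:cds:forward"))),
    mechanisms = list(mech_simple_transcription(),
                      mech_simple_translation()),
    parameters = c(ktx = 0.1, ktl = 0.5))
  crn <- suppressMessages(compile_crn(m))
  sn <- species_names(crn)
  expect_true(all(c("dna_plasmid", "rna_plasmidtx1", "rna_plasmidtx5",
                    "protein_gfp", "protein_rfp") %in% sn))
  # 2 transcription + 2 translation reactions
  expect_identical(n_reactions(crn), 4L)
  # run-off transcription unit 2 still transcribes u2-rfp
  displayed <- vapply(crn$reactions, reaction_display, character(1))
  expect_true("rna_plasmidtx5 --0.5--> rna_plasmidtx5 + protein_rfp" %in%
                displayed)
})

test_that("construct strings parse and validate", {
  parts <- parse_construct_string("a:promoter:fwd, b:cds:rev")
  expect_identical(parts$orientation, c("fwd", "rev"))
  expect_error(parse_construct_string("a:promoter"), "malformed")
  expect_error(dna_construct("x", "a:gene:forward"), "unknown part types")
  expect_error(dna_construct("x", "a:promoter:up"), "unknown orientations")
  expect_error(dna_construct("x", ""), "empty construct")
})
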