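dna <- crn_species("X", "dna")
rna <- crn_species("X", "rna")
prot <- crn_species("X", "protein")
P <- crn_species("P")
R <- crn_species("R")

rx_serials <- function(upd) {
  sort(vapply(upd$reactions, reaction_display, character(1)))
}

test_that("simple transcription/translation emit one catalytic reaction", {
  tx <- simple_transcription_update(dna, rna, 0.1)
  expect_length(tx$reactions, 1)
  expect_identical(reaction_display(tx$reactions[[1]]),
                   "dna_X --0.1--> dna_X + rna_X")
  tl <- simple_translation_update(rna, prot, 0.5)
  expect_identical(reaction_display(tl$reactions[[1]]),
                   "rna_X --0.5--> rna_X + protein_X")
  # zero rates keep the structure
  expect_length(simple_transcription_update(dna, rna, 0)$reactions, 1)
  expect_error(simple_transcription_update(dna, dna, 0.1), "autocatalysis")
  expect_error(simple_translation_update(rna, rna, 0.5), "autocatalysis")
})

test_that("MM transcription is the bind/unbind/produce triple", {
  tx <- mm_transcription_update(dna, rna, P, 100, 10, 0.1)
  expect_length(tx$reactions, 3)
  expect_setequal(vapply(tx$species, canonical_name, character(1)),
                  c("dna_X", "none_P", "complex_dna_X_none_P", "rna_X"))
  expect_setequal(rx_serials(tx),
                  c("dna_X + P --100--> dna_X:P",
                    "dna_X:P --10--> dna_X + P",
                    "dna_X:P --0.1--> dna_X + P + rna_X"))
  # irreversible-binding limit still emits the rate-0 reverse reaction
  tx0 <- mm_transcription_update(dna, rna, P, 100, 0, 0.1)
  expect_length(tx0$reactions, 3)
})

test_that("MM translation mirrors MM transcription on (rna, R, protein)", {
  tl <- mm_translation_update(rna, prot, R, 100, 10, 0.5)
  expect_setequal(vapply(tl$species, canonical_name, character(1)),
                  c("rna_X", "none_R", "complex_rna_X_none_R", "protein_X"))
  expect_setequal(rx_serials(tl),
                  c("rna_X + R --100--> rna_X:R",
                    "rna_X:R --10--> rna_X + R",
                    "rna_X:R --0.5--> rna_X + R + protein_X"))
})

test_that("hill transcription saturates correctly in the regulator", {
  reg <- crn_species("B", "protein")
  tx <- hill_transcription_update(dna, rna, reg, "negative",
                                  ktx = 0.1, K = 20, n = 2)
  expect_length(tx$reactions, 1)
  p <- tx$reactions[[1]]$propensity
  st0 <- c(dna_X = 2, protein_B = 0)
  # no repressor: full rate ktx * [dna]
  expect_equal(evaluate_propensity(p, list(), st0), 0.1 * 2)
  # saturating repressor: rate -> 0
  expect_lt(evaluate_propensity(p, list(),
                                c(dna_X = 2, protein_B = 1e9)), 1e-12)
  # activation + repression partition ktx * [dna]
  txp <- hill_transcription_update(dna, rna, reg, "positive",
                                   ktx = 0.1, K = 20, n = 2)
  st <- c(dna_X = 2, protein_B = 13)
  expect_equal(evaluate_propensity(p, list(), st) +
                 evaluate_propensity(txp$reactions[[1]]$propensity,
                                     list(), st),
               0.1 * 2, tolerance = 1e-12)
  # leak adds a separate mass-action reaction
  txl <- hill_transcription_update(dna, rna, reg, "negative",
                                   ktx = 0.1, K = 20, n = 2, leak = 0.01)
  expect_length(txl$reactions, 2)
  expect_error(hill_transcription_update(dna, rna, reg, "negative",
                                         ktx = 0.1, K = 0, n = 2), "> 0")
})

test_that("multi-occupancy m=1 is reaction-for-reaction MM transcription", {
  mo <- multi_occupancy_transcription_update(dna, rna, P, 1, 100, 10, 0.1)
  mm <- mm_transcription_update(dna, rna, P, 100, 10, 0.1)
  expect_identical(rx_serials(mo), rx_serials(mm))
})

test_that("multi-occupancy states and rates follow the occupancy ladder", {
  # independent enumeration of the expected m=2 ladder
  G <- "dna_X"; G1 <- "dna_X:P"; G2 <- "dna_X:P:P"
  expected <- c(
    paste0(G, " + P --100--> ", G1),
    paste0(G1, " --10--> ", G, " + P"),
    paste0(G1, " --0.1--> ", G, " + P + rna_X"),
    paste0(G1, " + P --100--> ", G2),
    paste0(G2, " --20--> ", G1, " + P"),
    paste0(G2, " --0.2--> ", G1, " + P + rna_X"))
  mo2 <- multi_occupancy_transcription_update(dna, rna, P, 2, 100, 10, 0.1)
  expect_identical(rx_serials(mo2), sort(expected))
  # m occupancy states + dna + P + transcript
  mo3 <- multi_occupancy_transcription_update(dna, rna, P, 3, 100, 10, 0.1)
  expect_length(mo3$species, 6)
  expect_length(mo3$reactions, 9)
  expect_error(
    multi_occupancy_transcription_update(dna, rna, P, 0, 1, 1, 1),
    "positive integer")
})

test_that("MM catalysis converts substrate to product via the bound complex", {
  E <- crn_species("E", "protein"); S <- crn_species("S"); Pr <- crn_species("Q")
  cat <- mm_catalysis_update(E, S, Pr, 100, 10, 1)
  expect_length(cat$reactions, 3)
  expect_true("complex_protein_E_none_S" %in%
                vapply(cat$species, canonical_name, character(1)))
  expect_error(mm_catalysis_update(E, S, S, 1, 1, 1), "both sides")
  # enzyme == substrate is permitted: the template applies verbatim
  self <- mm_catalysis_update(S, S, Pr, 1, 1, 1)
  expect_true("complex_none_S_none_S" %in%
                vapply(self$species, canonical_name, character(1)))
})

test_that("one-step binding handles hetero-, homo- and ternary complexes", {
  A <- crn_species("A"); B <- crn_species("B"); C <- crn_species("C")
  ab <- one_step_binding_update(list(A, B), 100, 10)
  expect_identical(rx_serials(ab),
                   sort(c("A + B --100--> A:B", "A:B --10--> A + B")))
  homo <- one_step_binding_update(list(A, A), 1, 1)
  expect_identical(reaction_display(homo$reactions[[1]]), "2 A --1--> A:A")
  tern <- one_step_binding_update(list(A, B, C), 1, 1)
  expect_identical(species_display(tern$species[[4]]), "A:B:C")
  expect_error(one_step_binding_update(list(A), 1, 1), "at least 2")
})

test_that("MM degradation consumes the target and conserves the machine", {
  M <- crn_species("M", "rna"); RNase <- crn_species("RNase")
  deg <- mm_degradation_update(M, RNase, 100, 10, 1)
  expect_length(deg$reactions, 3)
  final <- deg$reactions[[3]]
  expect_identical(reaction_display(final), "rna_M:RNase --1--> RNase")
  # outputs of the degradation step contain the machine only
  expect_identical(vapply(final$outputs, canonical_name, character(1)),
                   "none_RNase")
  # the full catalytic cycle (bind then degrade) has zero net machinery
  expect_identical(net_stoich(deg$reactions[[1]], RNase) +
                     net_stoich(deg$reactions[[3]], RNase), 0L)
})

test_that("machinery has zero net stoichiometry over every MM cycle", {
  cycles <- list(
    list(mm_transcription_update(dna, rna, P, 1, 1, 1), P),
    list(mm_translation_update(rna, prot, R, 1, 1, 1), R),
    list(mm_catalysis_update(crn_species("E", "protein"),
                             crn_species("S"), crn_species("Q"),
                             1, 1, 1), crn_species("E", "protein")))
  for (cy in cycles) {
    upd <- cy[[1]]; machine <- cy[[2]]
    # binding + catalytic step cancel; unbinding reverses binding
    expect_identical(net_stoich(upd$reactions[[1]], machine) +
                       net_stoich(upd$reactions[[3]], machine), 0L)
    expect_identical(net_stoich(upd$reactions[[2]], machine),
                     -net_stoich(upd$reactions[[1]], machine))
  }
})

test_that("schema updates are pure functions", {
  u1 <- mm_transcription_update(dna, rna, P, 100, 10, 0.1)
  u2 <- mm_transcription_update(dna, rna, P, 100, 10, 0.1)
  expect_identical(rx_serials(u1), rx_serials(u2))
  expect_identical(vapply(u1$species, canonical_name, character(1)),
                   vapply(u2$species, canonical_name, character(1)))
})

test_that("every update's reactions stay inside its returned species set", {
  updates <- list(
    simple_transcription_update(dna, rna, 0.1),
    mm_transcription_update(dna, rna, P, 1, 1, 1),
    multi_occupancy_transcription_update(dna, rna, P, 3, 1, 1, 1),
    hill_transcription_update(dna, rna, crn_species("B", "protein"),
                              "negative", 1, 2, 2),
    mm_degradation_update(rna, crn_species("RNase"), 1, 1, 1))
  for (upd in updates) {
    declared <- vapply(upd$species, canonical_name, character(1))
    touched <- unlist(lapply(upd$reactions, function(r)
      vapply(c(r$inputs, r$outputs), canonical_name, character(1))))
    expect_true(all(touched %in% declared))
  }
})

test_that("the mechanism registry resolves built-ins and rejects unknowns", {
  expect_s3_class(get_mechanism("simple_transcription"), "crn_mechanism")
  expect_true(all(c("mm_transcription", "hill_transcription_negative",
                    "one_step_binding") %in% registered_mechanisms()))
  expect_error(get_mechanism("integrase_recombination"), "unknown mechanism")
})
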