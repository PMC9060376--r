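simple_ctx <- function(params = c(kb = 100, ku = 10, ktx = 0.1, ktl = 0.5),
                       mechs = list(mech_simple_transcription(),
                                    mech_simple_translation())) {
  names(mechs) <- vapply(mechs, `[[`, character(1), "mechanism_type")
  crnforge:::compile_context(mechs, parameter_db(params))
}

test_that("mechanism resolution prefers local over mixture", {
  local_hill <- mech_hill_transcription("negative")
  comp <- dna_assembly("rep", promoter = "prom", regulator = "q",
                       mechanisms = list(transcription = local_hill))
  mix_mechs <- list(transcription = mech_simple_transcription())
  expect_identical(
    resolve_mechanism(comp, mix_mechs, "transcription")$name,
    "hill_negative_transcription")
  bare <- dna_assembly("x", promoter = "prom")
  expect_identical(resolve_mechanism(bare, mix_mechs, "transcription")$name,
                   "simple_transcription")
  err <- tryCatch(resolve_mechanism(bare, mix_mechs, "translation"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "'x'")
  expect_match(err, "translation")
})

test_that("parameter resolution is component database first", {
  mech <- mech_simple_transcription()
  mix_db <- parameter_db(c(ktx = 0.1))
  local <- dna_assembly("X", promoter = "prom",
                        parameters = c(ktx = 9))
  expect_identical(resolve_parameter(local, mix_db, mech, "ktx"), 9)
  bare <- dna_assembly("X", promoter = "prom")
  expect_identical(resolve_parameter(bare, mix_db, mech, "ktx"), 0.1)
  err <- tryCatch(resolve_parameter(local, mix_db, mech, "kq"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "component database")
  expect_match(err, "mixture database")
})

test_that("sub-part names are a secondary part_id tier", {
  mech <- mech_simple_transcription()
  db <- parameter_db(tibble::tibble(
    mechanism = c(NA, NA, NA), part_id = c("X", "prom", NA), name = "ktx",
    value = c(1, 2, 3)))
  comp <- dna_assembly("X", promoter = "prom")
  # assembly-level beats promoter-level beats global
  expect_identical(
    resolve_parameter(comp, db, mech, "ktx", extra_part_ids = "prom"), 1)
  db2 <- parameter_db(tibble::tibble(
    mechanism = c(NA, NA), part_id = c("prom", NA), name = "ktx",
    value = c(2, 3)))
  expect_identical(
    resolve_parameter(comp, db2, mech, "ktx", extra_part_ids = "prom"), 2)
})

test_that("a DNA assembly compiles the expression cascade it declares", {
  ctx <- simple_ctx()
  full <- dna_assembly("X", promoter = "prom", rbs = "rbs", protein = "X")
  upd <- component_update(full, ctx)
  expect_identical(
    sort(vapply(upd$reactions, reaction_display, character(1))),
    sort(c("dna_X --0.1--> dna_X + rna_X",
           "rna_X --0.5--> rna_X + protein_X")))
  # promoter only: transcription only, no orphan translation
  tx_only <- component_update(
    dna_assembly("X", promoter = "prom"), ctx)
  expect_length(tx_only$reactions, 1)
  # no promoter at all: just the DNA species
  bare <- component_update(dna_assembly("X"), ctx)
  expect_length(bare$reactions, 0)
  expect_identical(canonical_name(bare$species[[1]]), "dna_X")
  expect_error(
    component_update(dna_assembly("X", promoter = "prom", rbs = "rbs"),
                     ctx),
    "no protein")
})

test_that("the same assembly under MM schemas compiles the machinery network", {
  ctx <- simple_ctx(mechs = list(mech_mm_transcription(crn_species("P")),
                                 mech_mm_translation(crn_species("R"))))
  upd <- component_update(
    dna_assembly("X", promoter = "prom", rbs = "rbs", protein = "X"), ctx)
  expect_length(upd$reactions, 6)
  expect_setequal(
    vapply(upd$species, canonical_name, character(1)),
    c("dna_X", "none_P", "complex_dna_X_none_P", "rna_X", "none_R",
      "complex_rna_X_none_R", "protein_X"))
})

test_that("chemical complexes bind their members in one step", {
  ctx <- simple_ctx(c(kb = 100, ku = 10),
                    mechs = list(mech_one_step_binding()))
  ab <- component_update(chemical_complex("cplx", c(A = 1, B = 1)), ctx)
  expect_identical(
    sort(vapply(ab$reactions, reaction_display, character(1))),
    sort(c("A + B --100--> A:B", "A:B --10--> A + B")))
  # homotetramer: 4A in a single step
  tetra <- component_update(chemical_complex("tetra", c(A = 4)), ctx)
  expect_identical(reaction_display(tetra$reactions[[1]]),
                   "4 A --100--> A:A:A:A")
  # members never defined elsewhere are auto-created untyped
  expect_identical(ab$species[[1]]$material, "none")
  expect_error(chemical_complex("one", c(A = 1)), "at least 2")
})

test_that("enzymes compile through the catalysis mechanism", {
  ctx <- simple_ctx(c(kb = 100, ku = 10, kcat = 1),
                    mechs = list(mech_mm_catalysis()))
  upd <- component_update(
    enzyme_component("lacZ", substrate = "lactose", product = "glucose"),
    ctx)
  expect_length(upd$reactions, 3)
  expect_true("complex_protein_lacZ_none_lactose" %in%
                vapply(upd$species, canonical_name, character(1)))
})

test_that("a self-contained component compiles identically in any mixture", {
  selfc <- dna_assembly(
    "X", promoter = "prom", rbs = "rbs", protein = "X",
    mechanisms = list(transcription = mech_simple_transcription(),
                      translation = mech_simple_translation()),
    parameters = c(ktx = 0.1, ktl = 0.5))
  mix1 <- crn_mixture("m1", components = list(selfc),
                      mechanisms = list(mech_mm_transcription(),
                                        mech_mm_translation()),
                      parameters = c(kb = 1, ku = 1, ktx = 99, ktl = 99))
  mix2 <- crn_mixture("m2", components = list(selfc))
  expect_identical(write_crn_text(compile_crn(mix1)),
                   write_crn_text(compile_crn(mix2)))
})

test_that("the component registry instantiates by type name", {
  ctor <- get_component_constructor("dna_assembly")
  expect_identical(ctor("Z", promoter = "p")$type, "dna_assembly")
  expect_true(all(c("enzyme", "chemical_complex", "dna_construct") %in%
                    registered_components()))
  expect_error(get_component_constructor("integrase"), "unknown component")
})
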