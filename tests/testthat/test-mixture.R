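test_that("the worked example compiles to the two-reaction network", {
  crn <- compile_crn(make_example_2_7("simple"))
  expect_identical(species_names(crn), c("dna_X", "rna_X", "protein_X"))
  expect_identical(n_reactions(crn), 2L)
  rates <- vapply(crn$reactions, function(r)
    r$propensity$parameters[["k"]], numeric(1))
  expect_identical(rates, c(0.1, 0.5))
})

test_that("swapping to MM schemas compiles the machinery network", {
  crn <- compile_crn(make_example_2_7("mm"))
  expect_setequal(species_names(crn),
                  c("dna_X", "none_P", "complex_dna_X_none_P", "rna_X",
                    "none_R", "complex_rna_X_none_R", "protein_X"))
  expect_identical(n_reactions(crn), 6L)
})

test_that("an empty mixture compiles to an empty network", {
  crn <- compile_crn(crn_mixture("empty"))
  expect_identical(n_species(crn), 0L)
  expect_identical(n_reactions(crn), 0L)
})

test_that("compilation is deterministic and read-only on the mixture", {
  m <- make_example_2_7("mm")
  before <- write_crn_text(compile_crn(m))
  after <- write_crn_text(compile_crn(m))
  expect_identical(before, after)
  expect_identical(export_sbml(compile_crn(m)),
                   export_sbml(compile_crn(m)))
})

test_that("adding a self-contained component never alters existing reactions", {
  base <- make_example_2_7("simple")
  crn1 <- compile_crn(base)
  bigger <- crn_mixture(base$name,
                        components = c(base$components,
                                       list(dna_assembly("Y",
                                                         promoter = "prom",
                                                         rbs = "rbs",
                                                         protein = "Y"))),
                        mechanisms = base$mechanisms,
                        parameters = base$parameters)
  crn2 <- compile_crn(bigger)
  old <- vapply(crn1$reactions, reaction_display, character(1))
  new <- vapply(crn2$reactions, reaction_display, character(1))
  expect_true(all(old %in% new))
  expect_identical(new[seq_along(old)], old)  # order preserved too
})

test_that("global mechanism filters select by material and attributes", {
  prot <- crn_species("GFP", "protein")
  P <- crn_species("P", attributes = "machinery")
  dil <- global_mechanism(mech_dilution(),
                          without_attributes = "machinery")
  m <- crn_mixture("dil", global_mechanisms = list(dil),
                   parameters = c(kdil = 0.01))
  out <- apply_global_mechanisms(m, list(prot, P))
  expect_length(out$reactions, 1)
  expect_identical(reaction_display(out$reactions[[1]]),
                   "protein_GFP --0.01--> 0")
  # no global mechanisms: identity
  none <- apply_global_mechanisms(crn_mixture("x"), list(prot))
  expect_length(none$reactions, 0)
})

test_that("global mechanisms run once and never recurse", {
  params <- c(kb = 100, ku = 10, ktx = 0.1, ktl = 0.5, kdeg = 1)
  m <- make_library_mixture(
    "txtl_machinery", parameters = params,
    components = list(dna_assembly("X", promoter = "prom", rbs = "rbs",
                                   protein = "X")))
  crn <- compile_crn(m)
  glog <- attr(crn, "global_mechanism_log")
  applied <- vapply(glog, `[[`, character(1), "applied_to")
  created <- unique(unlist(lapply(glog, `[[`, "created")))
  # degradation targeted the transcript only
  expect_identical(applied, "rna_X")
  # species created in the global step were never fed back in
  expect_length(intersect(applied, created), 0L)
  # the rna:RNase complex exists but receives no further degradation
  expect_true("complex_rna_X_none_RNase_machinery" %in% species_names(crn))
  deg_inputs <- unique(unlist(lapply(glog, `[[`, "inputs")))
  expect_false("complex_rna_X_none_RNase_machinery" %in% applied)
  # and the full network contains the three degradation reactions
  expect_identical(n_reactions(crn), 9L)
})

test_that("library mixtures bundle the documented schema sets", {
  params <- c(kb = 100, ku = 10, ktx = 0.1, ktl = 0.5, kdeg = 1)
  G <- dna_assembly("X", promoter = "prom", rbs = "rbs", protein = "X")
  simple <- compile_crn(make_library_mixture("expression_simple",
                                             params, list(G)))
  expect_identical(n_reactions(simple), 2L)
  mm <- compile_crn(make_library_mixture("expression_mm", params, list(G)))
  expect_identical(n_reactions(mm), 6L)
  txtl <- compile_crn(make_library_mixture("txtl_machinery", params,
                                           list(G)))
  displayed <- vapply(txtl$reactions, reaction_display, character(1))
  expect_true(any(grepl("rna_X \\+ RNase_machinery --100-->", displayed)))
  expect_true(any(grepl("--1--> RNase_machinery$", displayed)))
  expect_error(make_library_mixture("in_vivo"), "unknown mixture kind")
})

test_that("initial concentrations come from the parameter database", {
  db <- merge_parameter_db(
    parameter_db(c(ktx = 0.1, ktl = 0.5)),
    parameter_db(tibble::tibble(mechanism = NA, part_id = "dna_X",
                                name = "initial_concentration", value = 5)))
  m <- crn_mixture("ic",
                   components = list(dna_assembly("X", promoter = "prom",
                                                  rbs = "rbs",
                                                  protein = "X")),
                   mechanisms = list(mech_simple_transcription(),
                                     mech_simple_translation()),
                   parameters = db)
  crn <- compile_crn(m)
  ic <- attr(crn, "initial")
  expect_identical(ic[["dna_X"]], 5)
  expect_identical(ic[["rna_X"]], 0)
})

test_that("the audit table has one row per parameter lookup", {
  crn <- compile_crn(make_example_2_7("simple"))
  audit <- params_audit(crn)
  expect_identical(nrow(audit), 2L)       # ktx and ktl
  expect_identical(sort(audit$parameter), c("ktl", "ktx"))
  expect_true(all(audit$tier == 6L))      # resolved from global defaults
  expect_true(all(audit$source == "mixture"))
  crn_mm <- compile_crn(make_example_2_7("mm"))
  expect_identical(nrow(params_audit(crn_mm)), 6L)
})
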