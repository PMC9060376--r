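test_that("databases build from named vectors and data frames", {
  db <- parameter_db(c(kb = 100, ku = 10, ktx = 0.1, ktl = 0.5))
  expect_identical(nrow(db), 4L)
  expect_true(all(is.na(db$mechanism)))
  expect_error(parameter_db(c(1, 2)), "named")
  expect_error(parameter_db(data.frame(name = "k")), "lacks columns")
  expect_error(
    parameter_db(data.frame(mechanism = NA, part_id = NA, name = "k",
                            value = NA_real_)), "finite")
})

# one entry per tier of the defaulting hierarchy, each with a unique value;
# removing entries top-down must walk the hierarchy in order
tier_db_rows <- tibble::tibble(
  mechanism = c("txmm1", "transcription", NA, "txmm1", "transcription", NA),
  part_id = c("prom1", "prom1", "prom1", NA, NA, NA),
  name = "kb",
  value = as.numeric(1:6)
)

test_that("find_parameter walks all six tiers most-specific first", {
  mech_args <- list(mechanism_name = "txmm1",
                    mechanism_type = "transcription", part_id = "prom1",
                    name = "kb")
  for (tier in 1:6) {
    db <- parameter_db(tier_db_rows[tier:6, ])
    hit <- do.call(find_parameter, c(list(db), mech_args))
    expect_identical(hit$value, as.numeric(tier))
    expect_identical(hit$tier, tier)
  }
})

test_that("an exact key is never shadowed by a less specific one", {
  db <- parameter_db(tier_db_rows)
  hit <- find_parameter(db, "txmm1", "transcription", "prom1", "kb")
  expect_identical(hit$value, 1)
  expect_identical(hit$key$mechanism, "txmm1")
  expect_identical(hit$key$part_id, "prom1")
})

test_that("global defaults serve unrelated mechanisms and parts", {
  db <- parameter_db(tibble::tibble(
    mechanism = c("transcription_mm", NA), part_id = c("prom1", NA),
    name = "kb", value = c(200, 100)))
  expect_identical(
    find_parameter(db, mechanism_type = "transcription_mm",
                   part_id = "prom1", name = "kb")$value, 200)
  expect_identical(
    find_parameter(db, mechanism_type = "translation_mm",
                   part_id = "rbs1", name = "kb")$value, 100)
})

test_that("a miss lists every attempted key in search order", {
  db <- parameter_db(c(kb = 100))
  err <- tryCatch(
    find_parameter(db, "txmm1", "transcription", "prom1", "kcat"),
    error = function(e) conditionMessage(e))
  expect_match(err, "(txmm1, prom1, kcat)", fixed = TRUE)
  expect_match(err, "(transcription, , kcat)", fixed = TRUE)
  expect_match(err, "(, , kcat)", fixed = TRUE)
})

test_that("secondary part candidates beat part-free tiers", {
  db <- parameter_db(tibble::tibble(
    mechanism = c(NA, NA), part_id = c("prom", NA), name = "ktx",
    value = c(9, 0.1)))
  hit <- find_parameter(db, part_id = c("X", "prom"), name = "ktx")
  expect_identical(hit$value, 9)
  expect_identical(hit$key$part_id, "prom")
})

test_that("adding entries never breaks a previously resolvable query", {
  db <- parameter_db(c(kb = 100, ktx = 0.1))
  bigger <- merge_parameter_db(db, parameter_db(tibble::tibble(
    mechanism = "transcription", part_id = "prom", name = "kb",
    value = 7)))
  for (nm in c("kb", "ktx")) {
    expect_silent(v1 <- find_parameter(db, name = nm)$value)
    expect_silent(v2 <- find_parameter(bigger, name = nm)$value)
    expect_identical(v1, v2)   # the old global keys still resolve
  }
})

write_param_file <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("parameter files load with auto-detected delimiters", {
  tsv <- write_param_file(c(
    "# ball-park defaults",
    "mechanism\tpart_id\tparam_name\tvalue",
    "\t\tkb\t100", "\t\tku\t10", "\t\tktx\t0.1", "\t\tktl\t0.5"))
  db <- load_parameter_file(tsv)
  expect_identical(nrow(db), 4L)
  expect_identical(find_parameter(db, name = "ktx")$value, 0.1)
  csv <- write_param_file(c("mechanism,part_id,param_name,value",
                            "transcription,prom,kb,42"), ".csv")
  db2 <- load_parameter_file(csv)
  expect_identical(db2$mechanism, "transcription")
  expect_identical(db2$value, 42)
})

test_that("duplicate keys warn and the last row wins", {
  path <- write_param_file(c("mechanism\tpart_id\tparam_name\tvalue",
                             "\t\tkb\t1", "\t\tkb\t2"))
  expect_warning(db <- load_parameter_file(path), "overrides")
  expect_identical(find_parameter(db, name = "kb")$value, 2)
})

test_that("malformed files fail with the offending line number", {
  short <- write_param_file(c("mechanism\tpart_id\tparam_name\tvalue",
                              "only\ttwo"))
  expect_error(load_parameter_file(short), "line 2")
  nonnum <- write_param_file(c("mechanism\tpart_id\tparam_name\tvalue",
                               "\t\tkb\tfast"))
  expect_error(load_parameter_file(nonnum), "non-numeric")
  expect_error(load_parameter_file(tempfile()), "not found")
  header_only <- write_param_file("mechanism\tpart_id\tparam_name\tvalue")
  expect_identical(nrow(load_parameter_file(header_only)), 0L)
})

test_that("write/load round-trips the entry set", {
  db <- parameter_db(tibble::tibble(
    mechanism = c("transcription", NA), part_id = c("prom", NA),
    name = c("kb", "ktl"), value = c(12.5, 0.5)))
  path <- tempfile(fileext = ".tsv")
  write_parameter_file(db, path)
  back <- load_parameter_file(path)
  expect_identical(back[, c("mechanism", "part_id", "name", "value")],
                   db[, c("mechanism", "part_id", "name", "value")])
})
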