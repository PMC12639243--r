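# Build a metadata-only store directly; QC operates on metadata, so these
# tests construct exactly the cross-cycle situation they need.
meta_store <- function(descr, vars, cb = NULL) {
  store <- snapshot_store()
  store$metadata <- list(
    descriptions = descr, variables = vars,
    codebook = if (is.null(cb)) nhanessnap:::empty_codebook() else cb)
  store
}

demo_family <- function(n, begin = 1999) {
  suffix <- c("", paste0("_", LETTERS[2:26]))[seq_len(n)]
  data.frame(table = paste0("DEMO", suffix),
             begin_year = begin + 2 * (seq_len(n) - 1),
             stringsAsFactors = FALSE)
}

test_that("qc_var flags label, description and target drift with partitions", {
  fam <- demo_family(4)
  descr <- do.call(rbind, lapply(seq_len(4), function(i)
    questionnaire_description(fam$table[i], "Demographics",
                              fam$begin_year[i], fam$begin_year[i] + 1)))
  vars <- do.call(rbind, lapply(seq_len(4), function(i)
    questionnaire_variable(
      "DMDEDUC3", fam$table[i],
      sas_label = if (i <= 2) "Education Level - Children/Youth 6-19"
                  else "Education level - Children/Youth 6-19",
      english_text = "Highest grade completed.",
      target = "Both males and females 6 YEARS - 19 YEARS")))
  store <- meta_store(descr, vars)
  f <- qc_var(store, "DMDEDUC3")
  expect_equal(finding_ids <- vapply(f, `[[`, character(1), "check_id"),
               "label_mismatch")
  expect_equal(sort(unname(lengths(f[[1L]]$tables))), c(2L, 2L))
  expect_setequal(unlist(f[[1L]]$tables), fam$table)
})

test_that("identical metadata yields no findings and scope is honoured", {
  fam <- demo_family(3)
  descr <- do.call(rbind, lapply(seq_len(3), function(i)
    questionnaire_description(fam$table[i], "Demographics",
                              fam$begin_year[i], fam$begin_year[i] + 1)))
  vars <- do.call(rbind, lapply(seq_len(3), function(i)
    questionnaire_variable("RIAGENDR", fam$table[i], sas_label = "Gender",
                           english_text = "Gender of the participant.")))
  store <- meta_store(descr, vars)
  expect_length(qc_var(store, "RIAGENDR"), 0L)
  expect_warning(res <- qc_var(store, "NOSUCH"), "not found")
  expect_length(res, 0L)

  # scoped check never reports tables outside the scope
  vars2 <- vars
  vars2$sas_label[3] <- "GENDER"
  store2 <- meta_store(descr, vars2)
  f <- qc_var(store2, "RIAGENDR", scope = fam$table[1:2])
  expect_length(f, 0L)
})

test_that("a variable in two tables of one cycle is flagged", {
  descr <- rbind(
    questionnaire_description("DEMO", "D", 1999, 2000),
    questionnaire_description("SMQ", "S", 1999, 2000))
  vars <- rbind(questionnaire_variable("RIAGENDR", "DEMO", sas_label = "Gender"),
                questionnaire_variable("RIAGENDR", "SMQ", sas_label = "Gender"))
  f <- qc_var(meta_store(descr, vars), "RIAGENDR")
  expect_equal(vapply(f, `[[`, character(1), "check_id"), "multi_table_in_cycle")
  expect_setequal(f[[1L]]$tables[["1999-2000"]], c("DEMO", "SMQ"))
})

test_that("case-variant levels partition tables like the education example", {
  fam <- demo_family(10)
  descr <- do.call(rbind, lapply(seq_len(10), function(i)
    questionnaire_description(fam$table[i], "Demographics",
                              fam$begin_year[i], fam$begin_year[i] + 1)))
  vars <- do.call(rbind, lapply(seq_len(10), function(i)
    questionnaire_variable("DMDEDUC3", fam$table[i], sas_label = "Education")))
  cb <- do.call(rbind, lapply(seq_len(10), function(i) {
    lab10 <- if (i <= 6) "10th Grade" else "10th grade"
    codebook_rows("DMDEDUC3", fam$table[i], c("1", "2", "."),
                  c("9th Grade", lab10, "Missing"), count = c(5L, 5L, 1L))
  }))
  store <- meta_store(descr, vars, cb)
  f <- qc_levels(store, "DMDEDUC3")
  expect_equal(vapply(f, `[[`, character(1), "check_id"), "level_variant")
  expect_setequal(lengths(f[[1L]]$tables), c(6L, 4L))
  expect_setequal(f[[1L]]$tables[["10th Grade"]], fam$table[1:6])
  expect_setequal(f[[1L]]$tables[["10th grade"]], fam$table[7:10])
})

test_that("level differences beyond normalisation are info, not variants", {
  fam <- demo_family(2)
  descr <- do.call(rbind, lapply(seq_len(2), function(i)
    questionnaire_description(fam$table[i], "D", fam$begin_year[i],
                              fam$begin_year[i] + 1)))
  vars <- do.call(rbind, lapply(seq_len(2), function(i)
    questionnaire_variable("EDU", fam$table[i])))
  cb <- rbind(
    codebook_rows("EDU", "DEMO", c("1", "."), c("Ninth grade", "Missing"),
                  c(5L, 0L)),
    codebook_rows("EDU", "DEMO_B", c("1", "."), c("9th grade", "Missing"),
                  c(5L, 0L)))
  f <- qc_levels(meta_store(descr, vars, cb), "EDU")
  expect_false("level_variant" %in% vapply(f, `[[`, character(1), "check_id"))
  expect_equal(vapply(f, `[[`, character(1), "severity"), "info")

  # byte-identical levels everywhere: nothing at all
  cb2 <- rbind(
    codebook_rows("EDU", "DEMO", c("1", "."), c("9th grade", "Missing"), c(5L, 0L)),
    codebook_rows("EDU", "DEMO_B", c("1", "."), c("9th grade", "Missing"), c(5L, 0L)))
  expect_length(qc_levels(meta_store(descr, vars, cb2), "EDU"), 0L)
})

test_that("unit changes are caught via label tokens and range midpoints", {
  fam <- demo_family(2)
  descr <- do.call(rbind, lapply(seq_len(2), function(i)
    questionnaire_description(fam$table[i], "Lab", fam$begin_year[i],
                              fam$begin_year[i] + 1)))
  mk_vars <- function(l1, l2) rbind(
    questionnaire_variable("LBCBHC", "DEMO", sas_label = l1,
                           english_text = "Beta-hexachlorocyclohexane."),
    questionnaire_variable("LBCBHC", "DEMO_B", sas_label = l2,
                           english_text = "Beta-hexachlorocyclohexane."))
  mk_cb <- function(r1, r2) rbind(
    codebook_rows("LBCBHC", "DEMO", c(r1, "."), c("Range of Values", "Missing"),
                  c(9L, 1L)),
    codebook_rows("LBCBHC", "DEMO_B", c(r2, "."), c("Range of Values", "Missing"),
                  c(9L, 1L)))

  # token change
  st <- meta_store(descr, mk_vars("Cadmium (nmol/L)", "Cadmium (ug/L)"),
                   mk_cb("0 to 5", "0 to 5"))
  f <- qc_units(st, "LBCBHC")
  expect_true("unit_change" %in% vapply(f, `[[`, character(1), "check_id"))

  # same token, 100x range shift
  st2 <- meta_store(descr, mk_vars("Cadmium (ug/L)", "Cadmium (ug/L)"),
                    mk_cb("0 to 5", "0 to 500"))
  f2 <- qc_units(st2, "LBCBHC")
  expect_equal(vapply(f2, `[[`, character(1), "check_id"), "unit_change")

  # identical everything: no findings
  st3 <- meta_store(descr, mk_vars("Cadmium (ug/L)", "Cadmium (ug/L)"),
                    mk_cb("0 to 5", "0 to 5"))
  expect_length(qc_units(st3, "LBCBHC"), 0L)
})

test_that("name reuse fires below the Jaccard threshold and not above", {
  fam <- demo_family(2)
  descr <- do.call(rbind, lapply(seq_len(2), function(i)
    questionnaire_description(fam$table[i], "Lab", fam$begin_year[i],
                              fam$begin_year[i] + 1)))
  mk <- function(t1, t2) rbind(
    questionnaire_variable("LBXHCT", "DEMO", english_text = t1),
    questionnaire_variable("LBXHCT", "DEMO_B", english_text = t2))

  f <- qc_name_reuse(meta_store(descr, mk(
    "Hematocrit (%)", "Hexachlorobenzene concentration in serum")), "LBXHCT")
  expect_equal(vapply(f, `[[`, character(1), "check_id"), "name_reuse")
  expect_equal(vapply(f, `[[`, character(1), "severity"), "error")

  expect_length(qc_name_reuse(meta_store(descr, mk(
    "Total cholesterol in serum", "Total cholesterol in serum")), "LBXHCT"), 0L)

  # paraphrase with high overlap stays quiet at the default threshold
  expect_length(qc_name_reuse(meta_store(descr, mk(
    "Total cholesterol measured in serum specimen",
    "Total cholesterol in serum specimen")), "LBXHCT"), 0L)
})

test_that("presence matrix reports per-file renames like the glyphosate files", {
  tabs <- c("SSGLYP_H", "SSGLYP_I", "SSGLYP_J")
  wts <- c("WTSSCH2Y", "WTSSGL2Y", "WTSSBJ2Y")
  descr <- do.call(rbind, lapply(seq_len(3), function(i)
    questionnaire_description(tabs[i], "Glyphosate", 2013 + 2 * (i - 1),
                              2014 + 2 * (i - 1))))
  vars <- do.call(rbind, lapply(seq_len(3), function(i) rbind(
    questionnaire_variable("SSGLYP", tabs[i],
                           english_text = "Glyphosate concentration in urine."),
    questionnaire_variable(wts[i], tabs[i],
                           english_text = "Subsample weight."))))
  res <- qc_presence_matrix(meta_store(descr, vars), tabs)
  expect_equal(dim(res$matrix), c(4L, 3L))
  expect_length(res$findings, 3L)
  for (f in res$findings) {
    expect_equal(f$check_id, "presence_gap")
    expect_true(f$variable %in% wts)
    expect_length(f$tables$absent, 2L)
    expect_length(f$tables$present, 1L)
  }
  # the shared analyte variable is present everywhere: no finding for it
  expect_false("SSGLYP" %in% vapply(res$findings, `[[`, character(1), "variable"))

  # identical variable sets: nothing
  vars2 <- do.call(rbind, lapply(seq_len(3), function(i)
    questionnaire_variable("SSGLYP", tabs[i])))
  expect_length(qc_presence_matrix(meta_store(descr, vars2), tabs)$findings, 0L)
})

test_that("a clean generated snapshot yields zero findings", {
  expect_length(qc_snapshot(default_release()$store), 0L)
})

test_that("every injected inconsistency is recalled with its check id", {
  ids <- qc_check_ids()
  for (k in seq_along(ids)) {
    spec <- fixture_spec(seed = 200L + k, n_cycles = 3L, n_per_cycle = 30L)
    spec <- inject(spec, random_injection(ids[k], 3L))
    dir <- file.path(tempdir(), paste0("inj-", ids[k]))
    unlink(dir, recursive = TRUE)
    invisible(make_snapshot(spec, dir))
    store <- build_snapshot_from_dir(dir)
    got <- vapply(qc_snapshot(store), `[[`, character(1), "check_id")
    expect_true(ids[k] %in% got, info = ids[k])
  }
})
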