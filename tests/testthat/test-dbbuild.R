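test_that("a built snapshot has the three namespaces and version info", {
  rel <- default_release()
  store <- rel$store
  n_tables <- nrow(rel$res$manifest)
  expect_length(store_tables(store, "raw"), n_tables)
  expect_length(store_tables(store, "translated"), n_tables)
  md <- metadata_tab(store, include_restricted = TRUE)
  expect_equal(nrow(md), n_tables)
  v <- version_info(store)
  expect_equal(v$variable, c("CONTAINER_VERSION", "COLLECTION_DATE"))
  expect_equal(v$value, c("t0", "2024-01-15"))
})

test_that("raw and translated namespaces resolve the same name differently", {
  store <- default_release()$store
  raw <- store_get_table(store, "DEMO", "raw")
  tr <- store_get_table(store, "DEMO", "translated")
  expect_identical(dim(raw), dim(tr))
  expect_true(is.numeric(raw$RIAGENDR))
  expect_true(is.character(tr$RIAGENDR))
  expect_setequal(unique(stats::na.omit(tr$RIAGENDR)), c("Male", "Female"))
  expect_identical(raw$SEQN, tr$SEQN)
})

test_that("excluded tables are skipped and logged; unknown tables error", {
  rel <- default_release()
  store <- build_snapshot_from_dir(rel$dir, exclusions = "BMX")
  expect_false("BMX" %in% store_tables(store, "raw"))
  expect_false("BMX" %in% metadata_tab(store)$table_name)
  expect_match(store$build_log, "excluded by config: BMX", all = FALSE)
  expect_error(store_get_table(store, "BMX", "raw"),
               class = "nhanessnap_not_found")
})

test_that("restricted tables keep metadata and documentation, not data", {
  tables <- default_fixture_tables <- nhanessnap:::default_fixture_tables()
  tables$SMQ$restricted <- TRUE
  spec <- fixture_spec(seed = 11L, n_cycles = 1L, n_per_cycle = 20L,
                       tables = tables)
  dir <- file.path(tempdir(), "restricted-rel")
  unlink(dir, recursive = TRUE)
  invisible(make_snapshot(spec, dir))
  store <- build_snapshot_from_dir(dir)
  expect_false("SMQ" %in% store_tables(store, "raw"))
  expect_false("SMQ" %in% metadata_tab(store)$table_name)
  expect_true("SMQ" %in% metadata_tab(store, include_restricted = TRUE)$table_name)
  # variables of the restricted table remain searchable
  expect_true("SMQ020" %in% metadata_var(store, "SMQ")$variable)
  # and its documentation is still served
  expect_match(serve_doc(store, "SMQ"), "SMQ020")
})

test_that("version info writes once and needs an explicit overwrite", {
  store <- snapshot_store()
  write_version_info(store, "0.9.0", "2024-01-15")
  v <- version_info(store)
  expect_equal(v$value, c("0.9.0", "2024-01-15"))
  expect_error(write_version_info(store, "1.0.0", "2024-02-01"), "overwrite")
  write_version_info(store, "1.0.0", "2024-02-01", overwrite = TRUE)
  expect_equal(version_info(store)$value[1L], "1.0.0")
  # version readable from a persisted store with no environment variables set
  dir <- file.path(tempdir(), "vstore")
  unlink(dir, recursive = TRUE)
  save_snapshot(store, dir)
  expect_equal(version_info(load_snapshot(dir))$value[1L], "1.0.0")
})

test_that("environment discovery requires the full variable set", {
  full <- c(NHANES_DB_VARIANT = "postgres", NHANES_DB_PORT = "5432",
            NHANES_TABLE_BASE = "/docs")
  env <- discover_environment(full)
  expect_true(env$present)
  expect_equal(env$port, 5432L)
  expect_equal(env$doc_base, "/docs")

  empty <- discover_environment(character())
  expect_false(empty$present)
  expect_length(empty$missing, 3L)

  expect_warning(part <- discover_environment(full[1:2]), "NHANES_TABLE_BASE")
  expect_false(part$present)
  expect_equal(part$missing, "NHANES_TABLE_BASE")
})

test_that("documentation round-trips byte-identically through serve_doc", {
  rel <- default_release()
  on_disk <- paste(readLines(file.path(rel$dir, "docs", "DEMO.htm"),
                             warn = FALSE), collapse = "\n")
  expect_identical(serve_doc(rel$store, "DEMO"), on_disk)
  expect_identical(serve_doc(file.path(rel$dir, "docs"), "DEMO"), on_disk)
  expect_error(serve_doc(rel$store, "NOPE"), class = "nhanessnap_not_found")
})

test_that("rebuilding from the same inputs is deterministic", {
  rel <- default_release()
  s1 <- build_snapshot_from_dir(rel$dir, "t0", "2024-01-15")
  s2 <- build_snapshot_from_dir(rel$dir, "t0", "2024-01-15")
  expect_equal(sort(store_tables(s1, "raw")), sort(store_tables(s2, "raw")))
  for (tn in store_tables(s1, "raw")) {
    expect_identical(store_get_table(s1, tn, "raw"),
                     store_get_table(s2, tn, "raw"))
    expect_identical(store_get_table(s1, tn, "translated"),
                     store_get_table(s2, tn, "translated"))
  }
  expect_identical(metadata_cb(s1), metadata_cb(s2))
})

test_that("pages in an unsupported dialect are excluded, not fatal", {
  rel <- default_release()
  dir <- file.path(tempdir(), "dialect-rel")
  unlink(dir, recursive = TRUE)
  for (f in list.files(rel$dir, recursive = TRUE)) {
    dir.create(dirname(file.path(dir, f)), recursive = TRUE,
               showWarnings = FALSE)
    file.copy(file.path(rel$dir, f), file.path(dir, f))
  }
  writeLines("<html><body><p>scanned PDF placeholder</p></body></html>",
             file.path(dir, "docs", "BMX.htm"))
  store <- build_snapshot_from_dir(dir)
  expect_false("BMX" %in% store_tables(store, "raw"))
  expect_match(store$build_log, "unsupported dialect.*BMX", all = FALSE)
  expect_true("DEMO" %in% store_tables(store, "raw"))
})
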