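test_that("emit-parse identity holds for generated documentation pages", {
  rel <- default_release()
  for (tn in names(rel$res$docs)) {
    emitted <- rel$res$docs[[tn]]
    parsed <- parse_doc_page(emit_doc_page(emitted), table_name = tn)
    expect_length(parsed$parse_warnings, 0L)
    expect_equal(length(parsed$variables), length(emitted$variables))
    for (i in seq_along(emitted$variables)) {
      a <- emitted$variables[[i]]
      b <- parsed$variables[[i]]
      expect_equal(b$var$variable, a$var$variable)
      expect_equal(b$var$sas_label, a$var$sas_label)
      expect_equal(b$var$english_text, a$var$english_text)
      expect_equal(b$var$target, a$var$target)
      expect_equal(b$codebook$code_or_value, a$codebook$code_or_value)
      expect_equal(b$codebook$value_description, a$codebook$value_description)
      expect_equal(b$codebook$count, a$codebook$count)
      expect_equal(b$codebook$cumulative, a$codebook$cumulative)
      expect_equal(b$codebook$skip_to_item, a$codebook$skip_to_item)
    }
  }
})

test_that("parsing is insensitive to whitespace-only reformatting", {
  doc <- smoking_doc()
  html <- emit_doc_page(doc)
  # re-serialise with different inter-tag whitespace
  mangled <- gsub("</dd>", "</dd>\n\n  ", html, fixed = TRUE)
  mangled <- gsub("<tr>", "\n   <tr>", mangled, fixed = TRUE)
  a <- parse_doc_page(html, "SMQ")
  b <- parse_doc_page(mangled, "SMQ")
  expect_equal(lapply(b$variables, `[[`, "codebook"),
               lapply(a$variables, `[[`, "codebook"))
})

test_that("skip targets are extracted and end-of-section is normalised", {
  doc <- smoking_doc()
  parsed <- parse_doc_page(emit_doc_page(doc), "SMQ")
  cb <- parsed$variables[[1L]]$codebook
  expect_equal(cb$skip_to_item[cb$code_or_value == "2"], "SMQ040")

  # an end-of-section phrasing normalises to the sentinel
  v <- questionnaire_variable("Q1", "T", "Gate", "Gate question.")
  cbr <- codebook_rows("Q1", "T", c("1", "2"), c("Yes", "No"),
                       count = c(1L, 1L),
                       skip_to_item = c(NA, skip_end_sentinel()))
  page <- emit_doc_page(codebook_doc("T", list(list(var = v, codebook = cbr))))
  expect_match(page, "End of Section")
  reparsed <- parse_doc_page(page, "T")
  expect_equal(reparsed$variables[[1L]]$codebook$skip_to_item[2L],
               skip_end_sentinel())
})

test_that("range rows and thousands separators survive parsing", {
  html <- paste0(
    "<html><head><title>LAB</title></head><body>",
    "<dl><dt>Variable Name:</dt><dd>LBXX</dd>",
    "<dt>SAS Label:</dt><dd>Thing (mg/dL)</dd></dl>",
    "<table><tr><th>Code or Value</th><th>Value Description</th>",
    "<th>Count</th><th>Cumulative</th><th>Skip to Item</th></tr>",
    "<tr><td>0 to 80</td><td>Range of Values</td><td>12,345</td>",
    "<td>12,345</td><td></td></tr>",
    "<tr><td>.</td><td>Missing</td><td>55</td><td>12,400</td><td></td></tr>",
    "</table></body></html>")
  doc <- parse_doc_page(html)
  expect_equal(doc$table_name, "LAB")
  cb <- doc$variables[[1L]]$codebook
  expect_equal(cb$code_or_value[1L], "0 to 80")
  expect_equal(cb$count, c(12345L, 55L))
  expect_equal(cb$cumulative, c(12345L, 12400L))
  expect_true(validate_codebook(cb))
})

test_that("unknown fields are warned about and pages without blocks fail", {
  html <- paste0(
    "<html><body><dl><dt>Variable Name:</dt><dd>XX1</dd>",
    "<dt>Mystery Field:</dt><dd>whatever</dd></dl>",
    "<table><tr><th>Code or Value</th><th>Value Description</th></tr>",
    "<tr><td>1</td><td>Yes</td></tr></table></body></html>")
  doc <- parse_doc_page(html, "T")
  expect_match(doc$parse_warnings, "Mystery Field", all = FALSE)
  # missing Count column -> counts absent, not zero
  expect_true(all(is.na(doc$variables[[1L]]$codebook$count)))

  err <- tryCatch(parse_doc_page("<html><body><p>nothing here</p></body></html>"),
                  condition = function(e) e)
  expect_s3_class(err, "nhanessnap_unsupported_dialect")
  expect_s3_class(err, "nhanessnap_parse_error")
  expect_true(is.integer(err$offset))
})

test_that("manifests parse from TSV and HTML with restricted flags", {
  tsv <- paste(
    "table_name\tdoc_file\tdata_file\tbegin_year\tend_year\tuse_constraints",
    "DEMO\tdocs/DEMO.htm\tdata/DEMO.csv\t1999\t2000\t",
    "PAX\tdocs/PAX.htm\tdata/PAX.csv\t1999\t2000\trestricted",
    sep = "\n")
  m <- parse_manifest(tsv)
  expect_equal(nrow(m), 2L)
  expect_equal(m$begin_year, c(1999L, 1999L))
  expect_equal(m$use_constraints, c("public", "restricted"))

  html <- paste0(
    "<html><body><table>",
    "<tr><th>table_name</th><th>doc_file</th><th>data_file</th>",
    "<th>begin_year</th><th>end_year</th><th>use_constraints</th></tr>",
    "<tr><td>DEMO</td><td>d.htm</td><td>d.csv</td><td>2001</td><td>2002</td>",
    "<td></td></tr></table></body></html>")
  mh <- parse_manifest(html)
  expect_equal(mh$table_name, "DEMO")
  expect_equal(mh$end_year, 2002L)
  expect_equal(mh$use_constraints, "public")

  empty <- parse_manifest("table_name\tdoc_file\tdata_file\tbegin_year\tend_year\n")
  expect_equal(nrow(empty), 0L)

  dup <- paste(
    "table_name\tdoc_file\tdata_file\tbegin_year\tend_year",
    "DEMO\ta\tb\t1999\t2000", "DEMO\tc\td\t1999\t2000", sep = "\n")
  expect_error(parse_manifest(dup), "duplicate")
})

test_that("extract_metadata conserves row counts and flags restricted docs", {
  rel <- default_release()
  docs <- rel$res$docs
  meta <- extract_metadata(docs, rel$res$manifest)
  expect_equal(nrow(meta$descriptions), length(docs))
  expect_equal(nrow(meta$variables),
               sum(vapply(docs, function(d) length(d$variables), integer(1))))
  expect_equal(nrow(meta$codebook),
               sum(vapply(docs, function(d)
                 sum(vapply(d$variables, function(v) nrow(v$codebook),
                            integer(1))), integer(1))))

  orphan <- codebook_doc("GHOST", list(list(
    var = questionnaire_variable("G1", "GHOST"),
    codebook = codebook_rows("G1", "GHOST", "1", "Yes", 1L))))
  expect_error(extract_metadata(c(docs, list(GHOST = orphan)), rel$res$manifest),
               "GHOST")
})
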