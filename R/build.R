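log_line <- function(store, ...) {
  store$build_log <- c(store$build_log, paste0(...))
  invisible(store)
}

#' Build a versioned snapshot store
#'
#' Assembles the three namespaces from parsed inputs: raw tables are loaded
#' verbatim (never altered), translated tables are produced from each raw
#' table and its documentation via [translate_table()], and the metadata
#' tables are extracted from the documentation set with [extract_metadata()].
#' Restricted tables keep their metadata and documentation but contribute no
#' raw or translated data; tables named in `exclusions` are skipped entirely
#' and recorded in the build log (mirroring a release policy of excluding
#' oversized or non-standard files).
#'
#' @param manifest A manifest from [parse_manifest()].
#' @param docs Named list of `codebook_doc` objects (one per table).
#' @param raw_tables Named list of raw data frames.
#' @param container_version,collection_date Version stamp (see
#'   [write_version_info()]).
#' @param exclusions Character vector of table names to skip.
#' @param doc_html Optional named list of the original HTML pages, stored so
#'   [serve_doc()] can guarantee documentation matches the data loaded.
#' @return A [snapshot_store()].
#' @export
build_snapshot <- function(manifest, docs, raw_tables,
                           container_version = "0.1.0",
                           collection_date = Sys.Date(),
                           exclusions = character(), doc_html = NULL) {
  store <- snapshot_store()
  keep <- !manifest$table_name %in% exclusions
  for (tn in manifest$table_name[!keep])
    log_line(store, "excluded by config: ", tn)
  manifest <- manifest[keep, , drop = FALSE]
  docs <- docs[intersect(names(docs), manifest$table_name)]

  meta <- extract_metadata(docs, manifest)
  store$metadata <- meta

  for (i in seq_len(nrow(manifest))) {
    tn <- manifest$table_name[i]
    restricted <- manifest$use_constraints[i] != "public"
    if (!is.null(doc_html[[tn]])) store$docs[[tn]] <- doc_html[[tn]]
    if (restricted) {
      log_line(store, "restricted (metadata only): ", tn)
      next
    }
    rawtab <- raw_tables[[tn]]
    if (is.null(rawtab)) {
      log_line(store, "no data file for table: ", tn)
      next
    }
    store_put_table(store, tn, rawtab, "raw")
    doc <- docs[[tn]]
    if (is.null(doc)) {
      log_line(store, "no documentation; raw only: ", tn)
      next
    }
    tr <- withCallingHandlers(
      translate_table(rawtab, doc),
      warning = function(w) {
        log_line(store, "translate ", tn, ": ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (!identical(dim(tr), dim(rawtab)))
      stop("translated/raw shape mismatch for ", tn, ": ",
           nrow(tr), "x", ncol(tr), " vs ", nrow(rawtab), "x", ncol(rawtab))
    store_put_table(store, tn, tr, "translated")
  }
  write_version_info(store, container_version, collection_date)
  store
}

read_raw_file <- function(path) {
  if (grepl("\\.xpt$", path, ignore.case = TRUE)) {
    if (requireNamespace("haven", quietly = TRUE))
      as.data.frame(haven::read_xpt(path))
    else if (requireNamespace("foreign", quietly = TRUE))
      foreign::read.xport(path)
    else stop("reading SAS transport files requires haven or foreign")
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Build a snapshot store from a release directory
#'
#' Reads a release tree as emitted by [make_snapshot()] (or mirrored from an
#' upstream source): the manifest, one documentation page per table, and the
#' data files (CSV or SAS transport format). Documentation pages the parser
#' cannot read (non-standard dialects) cause the table to be excluded and
#' logged rather than aborting the build.
#'
#' @param dir Release directory containing `manifest.tsv` (or
#'   `manifest.html`).
#' @param container_version,collection_date Version stamp.
#' @param exclusions Table names to skip.
#' @return A [snapshot_store()].
#' @export
build_snapshot_from_dir <- function(dir, container_version = "0.1.0",
                                    collection_date = Sys.Date(),
                                    exclusions = character()) {
  mf <- c(file.path(dir, "manifest.tsv"), file.path(dir, "manifest.html"))
  mf <- mf[file.exists(mf)]
  if (length(mf) == 0L) stop("no manifest found under ", dir)
  manifest <- parse_manifest(mf[1L])

  docs <- list()
  doc_html <- list()
  unparseable <- character()
  for (i in seq_len(nrow(manifest))) {
    tn <- manifest$table_name[i]
    path <- file.path(dir, manifest$doc_file[i])
    if (!file.exists(path)) next
    html <- paste(readLines(path, warn = FALSE), collapse = "\n")
    doc_html[[tn]] <- html
    doc <- tryCatch(parse_doc_page(html, table_name = tn, source_path = path),
                    nhanessnap_parse_error = function(e) e)
    if (inherits(doc, "condition")) {
      unparseable <- c(unparseable, tn)
      next
    }
    docs[[tn]] <- doc
  }

  raw_tables <- list()
  for (i in seq_len(nrow(manifest))) {
    tn <- manifest$table_name[i]
    if (manifest$use_constraints[i] != "public") next
    if (tn %in% c(exclusions, unparseable)) next
    path <- file.path(dir, manifest$data_file[i])
    if (file.exists(path)) raw_tables[[tn]] <- read_raw_file(path)
  }

  store <- build_snapshot(manifest, docs, raw_tables,
                          container_version = container_version,
                          collection_date = collection_date,
                          exclusions = c(exclusions, unparseable),
                          doc_html = doc_html)
  for (tn in unparseable)
    log_line(store, "excluded (documentation in unsupported dialect): ", tn)
  store
}
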