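#' Create an empty snapshot store
#'
#' A snapshot store is the package's versioned container for one data release:
#' three namespaces (`raw`, `translated`, `metadata`) plus a `VersionInfo`
#' record and the HTML documentation pages. The in-memory backend is an
#' environment-backed registry of data frames; [save_snapshot()] and
#' [load_snapshot()] persist it as a directory of plain-text files. A
#' relational backend can sit behind the same registry interface.
#'
#' @return An object of class `snapshot_store`.
#' @export
snapshot_store <- function() {
  st <- new.env(parent = emptyenv())
  st$raw <- list()
  st$translated <- list()
  st$metadata <- NULL
  st$version <- NULL
  st$docs <- list()        # table_name -> HTML text
  st$build_log <- character()
  class(st) <- "snapshot_store"
  st
}

#' @export
print.snapshot_store <- function(x, ...) {
  cat("<snapshot_store>\n")
  cat("  raw tables:       ", length(x$raw), "\n")
  cat("  translated tables:", length(x$translated), "\n")
  cat("  metadata:         ",
      if (is.null(x$metadata)) "absent" else
        paste0(nrow(x$metadata$descriptions), " tables / ",
               nrow(x$metadata$variables), " variables / ",
               nrow(x$metadata$codebook), " codebook rows"), "\n")
  if (!is.null(x$version))
    cat("  version:           ", x$version$value[1L], " (",
        x$version$value[2L], ")\n", sep = "")
  invisible(x)
}

store_metadata <- function(store) {
  if (is.null(store$metadata)) stop_missing_schema("metadata")
  store$metadata
}

#' List table names in a store namespace
#' @param store A [snapshot_store()].
#' @param namespace One of `"raw"` or `"translated"`.
#' @return Character vector of table names.
#' @export
store_tables <- function(store, namespace = c("raw", "translated")) {
  namespace <- match.arg(namespace)
  names(store[[namespace]])
}

#' Retrieve a table from a store namespace
#'
#' The same table name resolves independently in the `raw` and `translated`
#' namespaces: the former holds the coded values as distributed, the latter
#' the character-labelled version.
#'
#' @inheritParams store_tables
#' @param table_name Name of the table.
#' @return A data frame.
#' @export
store_get_table <- function(store, table_name, namespace = c("raw", "translated")) {
  namespace <- match.arg(namespace)
  tab <- store[[namespace]][[table_name]]
  if (is.null(tab))
    stop(structure(
      class = c("nhanessnap_not_found", "error", "condition"),
      list(message = paste0("table ", table_name, " not found in ", namespace,
                            " namespace"), call = sys.call(-1))
    ))
  tab
}

store_put_table <- function(store, table_name, value,
                            namespace = c("raw", "translated")) {
  namespace <- match.arg(namespace)
  store[[namespace]][[table_name]] <- value
  invisible(store)
}

#' Record snapshot version information
#'
#' Writes the two-field `VersionInfo` record (container version and data
#' collection date). A second write fails unless `overwrite = TRUE`, so a
#' built snapshot carries exactly one version record.
#'
#' @param store A [snapshot_store()].
#' @param container_version Version string for the snapshot build.
#' @param collection_date Date the source data were collected/synced.
#' @param overwrite Allow replacing an existing record.
#' @return The store, invisibly.
#' @export
write_version_info <- function(store, container_version, collection_date,
                               overwrite = FALSE) {
  if (!is.null(store$version) && !overwrite)
    stop("VersionInfo already written; use overwrite = TRUE to replace it")
  store$version <- data.frame(
    variable = c("CONTAINER_VERSION", "COLLECTION_DATE"),
    value = c(as.character(container_version),
              as.character(as.Date(collection_date))),
    stringsAsFactors = FALSE
  )
  invisible(store)
}

#' Read snapshot version information
#' @param store A [snapshot_store()].
#' @return The two-row `VersionInfo` data frame.
#' @export
version_info <- function(store) {
  if (is.null(store$version)) stop_missing_schema("VersionInfo")
  store$version
}

# Environment variables making up the container discovery contract. Only the
# documentation-base name is fixed upstream; the others are this package's
# documented constants.
.ENV_VARS <- c(db_variant = "NHANES_DB_VARIANT",
               port = "NHANES_DB_PORT",
               doc_base = "NHANES_TABLE_BASE")

#' Discover a containerised deployment from environment variables
#'
#' Containerised deployments advertise themselves through environment
#' variables: the database variant, the port it listens on, and
#' `NHANES_TABLE_BASE`, the directory holding the HTML documentation inside
#' the container. When the full set is present, tools can connect
#' automatically; otherwise they fall back to file-based access and behave
#' identically.
#'
#' @param env Named character vector of environment variables; defaults to
#'   [Sys.getenv()].
#' @return A list with `present` (logical), `db_variant`, `port` (integer),
#'   `doc_base`, and `missing` (names of absent variables).
#' @export
discover_environment <- function(env = NULL) {
  if (is.null(env)) env <- Sys.getenv()
  env <- as.list(env)
  vals <- lapply(.ENV_VARS, function(v) {
    x <- env[[v]]
    if (is.null(x) || !nzchar(x)) NA_character_ else as.character(x)
  })
  missing <- .ENV_VARS[vapply(vals, is.na, logical(1))]
  if (length(missing)) {
    if (length(missing) < length(.ENV_VARS))
      warning("incomplete container environment; missing: ",
              paste(missing, collapse = ", "), call. = FALSE)
    return(list(present = FALSE, db_variant = NA_character_,
                port = NA_integer_, doc_base = NA_character_,
                missing = unname(missing)))
  }
  list(present = TRUE, db_variant = vals$db_variant,
       port = as.integer(vals$port), doc_base = vals$doc_base,
       missing = character())
}

#' Serve the documentation page for a table
#'
#' Returns the stored HTML for a table, either from a built store or from a
#' documentation base directory (as advertised via `NHANES_TABLE_BASE`).
#' Serving the stored copy guarantees the documentation shown matches the
#' data that were loaded. Documentation is available for all tables,
#' including restricted-access ones whose data are absent.
#'
#' @param x A [snapshot_store()] or a directory path.
#' @param table_name Table whose page to serve.
#' @return The page as a single character string.
#' @export
serve_doc <- function(x, table_name) {
  if (inherits(x, "snapshot_store")) {
    doc <- x$docs[[table_name]]
    if (is.null(doc))
      stop(structure(
        class = c("nhanessnap_not_found", "error", "condition"),
        list(message = paste0("no documentation stored for table ", table_name),
             call = sys.call(-1))
      ))
    return(doc)
  }
  for (ext in c(".htm", ".html")) {
    path <- file.path(x, paste0(table_name, ext))
    if (file.exists(path))
      return(paste(readLines(path, warn = FALSE), collapse = "\n"))
  }
  stop(structure(
    class = c("nhanessnap_not_found", "error", "condition"),
    list(message = paste0("no documentation file for table ", table_name,
                          " under ", x), call = sys.call(-1))
  ))
}

write_store_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

#' Persist a snapshot store to a directory
#'
#' Writes the store as a tree of plain-text files: one CSV per table under
#' `raw/` and `translated/`, the three metadata tables plus `version.json`
#' under `metadata/`, the documentation pages under `docs/`, and the build
#' log. [load_snapshot()] restores it.
#'
#' @param store A [snapshot_store()].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_snapshot <- function(store, dir) {
  for (d in c("", "raw", "translated", "metadata", "docs"))
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  for (nm in names(store$raw))
    write_store_csv(store$raw[[nm]], file.path(dir, "raw", paste0(nm, ".csv")))
  for (nm in names(store$translated))
    write_store_csv(store$translated[[nm]],
                    file.path(dir, "translated", paste0(nm, ".csv")))
  if (!is.null(store$metadata)) {
    md <- store$metadata
    write_store_csv(md$descriptions, file.path(dir, "metadata", "descriptions.csv"))
    vars <- md$variables
    vars$target <- collapse_target(vars$target)
    write_store_csv(vars, file.path(dir, "metadata", "variables.csv"))
    write_store_csv(md$codebook, file.path(dir, "metadata", "codebook.csv"))
  }
  if (!is.null(store$version))
    jsonlite::write_json(as.list(stats::setNames(store$version$value,
                                                 store$version$variable)),
                         file.path(dir, "metadata", "version.json"),
                         auto_unbox = TRUE)
  for (nm in names(store$docs))
    writeLines(store$docs[[nm]], file.path(dir, "docs", paste0(nm, ".htm")))
  writeLines(store$build_log, file.path(dir, "build_log.txt"))
  invisible(dir)
}

read_store_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}

# Metadata string fields are never-missing strings in the model; restore ""
# for cells that the CSV round trip turned into NA.
na_to_empty <- function(df, except = character()) {
  for (col in setdiff(names(df), except))
    if (is.character(df[[col]]) || all(is.na(df[[col]])))
      df[[col]] <- ifelse(is.na(df[[col]]), "", as.character(df[[col]]))
  df
}

#' Load a snapshot store from a directory
#' @param dir Directory written by [save_snapshot()].
#' @return A [snapshot_store()].
#' @export
load_snapshot <- function(dir) {
  store <- snapshot_store()
  for (ns in c("raw", "translated")) {
    files <- list.files(file.path(dir, ns), pattern = "\\.csv$", full.names = TRUE)
    for (f in files)
      store[[ns]][[tools::file_path_sans_ext(basename(f))]] <- read_store_csv(f)
  }
  mdir <- file.path(dir, "metadata")
  if (file.exists(file.path(mdir, "descriptions.csv"))) {
    vars <- read_store_csv(file.path(mdir, "variables.csv"))
    vars$target <- split_target(ifelse(is.na(vars$target), "", vars$target))
    cb <- read_store_csv(file.path(mdir, "codebook.csv"))
    cb$code_or_value <- as.character(cb$code_or_value)
    cb <- na_to_empty(cb, except = c("count", "cumulative", "skip_to_item"))
    store$metadata <- list(
      descriptions = na_to_empty(
        read_store_csv(file.path(mdir, "descriptions.csv")),
        except = c("begin_year", "end_year")),
      variables = na_to_empty(vars, except = "target"), codebook = cb
    )
  }
  vfile <- file.path(mdir, "version.json")
  if (file.exists(vfile)) {
    v <- jsonlite::read_json(vfile)
    store$version <- data.frame(variable = names(v),
                                value = unlist(v, use.names = FALSE),
                                stringsAsFactors = FALSE)
  }
  dfiles <- list.files(file.path(dir, "docs"), pattern = "\\.html?$",
                       full.names = TRUE)
  for (f in dfiles)
    store$docs[[tools::file_path_sans_ext(basename(f))]] <-
      paste(readLines(f, warn = FALSE), collapse = "\n")
  logfile <- file.path(dir, "build_log.txt")
  if (file.exists(logfile)) store$build_log <- readLines(logfile, warn = FALSE)
  store
}
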