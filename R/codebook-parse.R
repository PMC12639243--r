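# Field labels recognised in variable blocks (document dialect). Real-page
# adapters can extend this mapping; unknown labels are recorded as parse
# warnings, never dropped silently.
.FIELD_MAP <- c(
  "Variable Name" = "variable",
  "SAS Label" = "sas_label",
  "English Text" = "english_text",
  "English Instructions" = "english_instructions",
  "Target" = "target",
  "Hard Edits" = "hard_edits"
)

.VALUE_HEADERS <- c("Code or Value", "Value Description", "Count",
                    "Cumulative", "Skip to Item")

stop_parse_error <- function(message, offset = 0L, dialect = FALSE) {
  cls <- c(if (dialect) "nhanessnap_unsupported_dialect",
           "nhanessnap_parse_error", "error", "condition")
  stop(structure(class = cls,
                 list(message = message, call = sys.call(-1),
                      offset = as.integer(offset))))
}

normalize_skip_target <- function(x) {
  x <- trimws(x)
  out <- ifelse(!nzchar(x) | x == ".", NA_character_, x)
  eos <- grepl("^end of (section|questionnaire)$", tolower(out))
  out[!is.na(out) & eos] <- .SKIP_END
  out[!is.na(out) & out == .SKIP_END] <- .SKIP_END
  out
}

parse_count <- function(x) {
  x <- gsub(",", "", trimws(x))
  suppressWarnings(as.integer(ifelse(nzchar(x), x, NA)))
}

#' Parse a codebook documentation page
#'
#' Parses one table's HTML documentation page into a `codebook_doc`: an
#' ordered list of variable blocks, each a metadata record plus its codebook
#' value rows. Variable blocks are recognised by a definition list carrying a
#' "Variable Name" field; the value table by its "Code or Value" header row.
#' Document order is preserved because it defines questionnaire order for
#' skip-logic analysis.
#'
#' @param html HTML text (single string or character vector of lines), or an
#'   `xml2` document.
#' @param table_name Table name; inferred from the page `<title>` if omitted.
#' @param source_path Optional provenance string stored on the result.
#' @return An object of class `codebook_doc` with elements `table_name`,
#'   `variables` (list of `list(var = <one-row data frame>, codebook =
#'   <data frame>)`), `source_path` and `parse_warnings`.
#' @export
parse_doc_page <- function(html, table_name = NULL, source_path = "") {
  if (inherits(html, "xml_document")) {
    doc <- html
    text <- as.character(html)
  } else {
    text <- paste(html, collapse = "\n")
    doc <- xml2::read_html(text)
  }
  warnings <- character()

  if (is.null(table_name)) {
    title <- xml2::xml_find_first(doc, "//title")
    if (!inherits(title, "xml_missing"))
      table_name <- trimws(sub(":.*$", "", xml2::xml_text(title)))
  }
  if (is.null(table_name) || !nzchar(table_name))
    table_name <- NA_character_

  nodes <- xml2::xml_find_all(doc, "//dl | //table")
  blocks <- list()
  current <- NULL
  flush <- function() {
    if (!is.null(current)) blocks[[length(blocks) + 1L]] <<- current
    current <<- NULL
  }

  for (node in nodes) {
    if (xml2::xml_name(node) == "dl") {
      fields <- parse_dl(node)
      if (!"Variable Name" %in% names(fields)) next
      flush()
      current <- list(fields = fields, rows = NULL)
    } else {
      tab <- parse_value_table(node)
      if (is.null(tab)) next
      if (is.null(current)) {
        warnings <- c(warnings, "value table found before any variable block; skipped")
        next
      }
      if (!is.null(current$rows))
        warnings <- c(warnings,
                      paste0("multiple value tables for variable ",
                             current$fields[["Variable Name"]][1L], "; extra kept"))
      current$rows <- rbind(current$rows, tab)
    }
  }
  flush()

  if (length(blocks) == 0L) {
    off <- regexpr("<body", text, fixed = TRUE)
    stop_parse_error(
      paste0("no recognizable variable block in documentation page",
             if (!is.na(table_name)) paste0(" for ", table_name)),
      offset = max(0L, off[1L]), dialect = TRUE
    )
  }

  variables <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    fields <- b$fields
    unknown <- setdiff(names(fields), names(.FIELD_MAP))
    vname <- fields[["Variable Name"]][1L]
    if (length(unknown))
      warnings <- c(warnings, paste0("unknown field(s) for ", vname, ": ",
                                     paste(unknown, collapse = ", ")))
    getf <- function(lbl) if (lbl %in% names(fields)) fields[[lbl]][1L] else ""
    var <- suppressWarnings(questionnaire_variable(
      variable = vname, table_name = table_name,
      sas_label = getf("SAS Label"), english_text = getf("English Text"),
      english_instructions = getf("English Instructions"),
      hard_edits = getf("Hard Edits"),
      target = if ("Target" %in% names(fields)) fields[["Target"]] else character()
    ))
    rows <- b$rows
    cb <- if (is.null(rows) || nrow(rows) == 0L) {
      empty_codebook()
    } else {
      codebook_rows(
        variable = vname, table_name = table_name,
        code_or_value = rows$code_or_value,
        value_description = rows$value_description,
        count = rows$count, cumulative = rows$cumulative,
        skip_to_item = rows$skip_to_item
      )
    }
    variables[[i]] <- list(var = var, codebook = cb)
  }

  structure(
    list(table_name = table_name, variables = variables,
         source_path = source_path, parse_warnings = warnings),
    class = "codebook_doc"
  )
}

parse_dl <- function(dl) {
  kids <- xml2::xml_children(dl)
  nm <- xml2::xml_name(kids)
  fields <- list()
  label <- NULL
  for (i in seq_along(kids)) {
    txt <- trimws(gsub("\\s+", " ", xml2::xml_text(kids[[i]])))
    if (nm[i] == "dt") {
      label <- sub(":$", "", txt)
    } else if (nm[i] == "dd" && !is.null(label)) {
      fields[[label]] <- c(fields[[label]], txt)
    }
  }
  fields
}

parse_value_table <- function(node) {
  rows <- xml2::xml_find_all(node, ".//tr")
  if (length(rows) == 0L) return(NULL)
  header <- vapply(xml2::xml_find_all(rows[[1L]], ".//th | .//td"),
                   function(x) trimws(gsub("\\s+", " ", xml2::xml_text(x))),
                   character(1))
  if (length(header) < 2L || header[1L] != "Code or Value") return(NULL)
  idx <- match(.VALUE_HEADERS, header)
  names(idx) <- c("code_or_value", "value_description", "count",
                  "cumulative", "skip_to_item")
  out <- list(code_or_value = character(), value_description = character(),
              count = integer(), cumulative = integer(),
              skip_to_item = character())
  body <- rows[-1L]
  cell_text <- function(r) vapply(xml2::xml_find_all(r, ".//td | .//th"),
                                  function(x) trimws(gsub("\\s+", " ", xml2::xml_text(x))),
                                  character(1))
  for (r in body) {
    cells <- cell_text(r)
    getc <- function(j) if (!is.na(j) && j <= length(cells)) cells[j] else ""
    out$code_or_value <- c(out$code_or_value, getc(idx["code_or_value"]))
    out$value_description <- c(out$value_description, getc(idx["value_description"]))
    out$count <- c(out$count,
                   if (is.na(idx["count"])) NA_integer_ else parse_count(getc(idx["count"])))
    out$cumulative <- c(out$cumulative,
                        if (is.na(idx["cumulative"])) NA_integer_
                        else parse_count(getc(idx["cumulative"])))
    out$skip_to_item <- c(out$skip_to_item,
                          normalize_skip_target(getc(idx["skip_to_item"])))
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' @export
print.codebook_doc <- function(x, ...) {
  cat("<codebook_doc> ", x$table_name, ": ", length(x$variables),
      " variable(s)\n", sep = "")
  for (v in x$variables)
    cat("  ", v$var$variable, " (", nrow(v$codebook), " codebook rows)\n", sep = "")
  if (length(x$parse_warnings))
    cat("  warnings:", length(x$parse_warnings), "\n")
  invisible(x)
}

doc_variable_names <- function(doc) {
  vapply(doc$variables, function(v) v$var$variable, character(1))
}

doc_codebook <- function(doc, variable) {
  for (v in doc$variables) if (v$var$variable == variable) return(v$codebook)
  NULL
}

#' Parse a release manifest
#'
#' A manifest is the list of tables making up one release: for each table its
#' documentation and data file locations, cycle years, and use constraints.
#' Both a tab-separated dialect (columns `table_name`, `doc_file`,
#' `data_file`, `begin_year`, `end_year`, and optionally `use_constraints`)
#' and an HTML table with the same columns are supported.
#'
#' @param x Manifest text, a file path, or an `xml2` document.
#' @return A data frame of class `nhanes_manifest`.
#' @export
parse_manifest <- function(x) {
  if (inherits(x, "xml_document")) {
    df <- parse_manifest_html(x)
  } else {
    txt <- if (length(x) == 1L && !grepl("[\n<]", x) && file.exists(x))
      paste(readLines(x, warn = FALSE), collapse = "\n") else paste(x, collapse = "\n")
    df <- if (grepl("^\\s*<", txt)) parse_manifest_html(xml2::read_html(txt))
    else parse_manifest_tsv(txt)
  }
  if (!"use_constraints" %in% names(df) || all(is.na(df$use_constraints)))
    df$use_constraints <- rep("public", nrow(df))
  df$use_constraints[!nzchar(df$use_constraints) | is.na(df$use_constraints)] <- "public"
  df$begin_year <- as.integer(df$begin_year)
  df$end_year <- as.integer(df$end_year)
  dup <- unique(df$table_name[duplicated(df$table_name)])
  if (length(dup))
    stop("duplicate table name(s) in manifest: ", paste(dup, collapse = ", "))
  class(df) <- c("nhanes_manifest", "data.frame")
  df
}

parse_manifest_tsv <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) <= 1L)
    return(data.frame(table_name = character(), doc_file = character(),
                      data_file = character(), begin_year = integer(),
                      end_year = integer(), use_constraints = character(),
                      stringsAsFactors = FALSE))
  utils::read.delim(text = paste(lines, collapse = "\n"),
                    stringsAsFactors = FALSE, na.strings = "")
}

parse_manifest_html <- function(doc) {
  rows <- xml2::xml_find_all(doc, "//table//tr")
  if (length(rows) == 0L)
    return(data.frame(table_name = character(), doc_file = character(),
                      data_file = character(), begin_year = integer(),
                      end_year = integer(), use_constraints = character(),
                      stringsAsFactors = FALSE))
  cells <- lapply(rows, function(r)
    vapply(xml2::xml_find_all(r, ".//th | .//td"),
           function(x) trimws(xml2::xml_text(x)), character(1)))
  header <- gsub("[^a-z_]", "_", tolower(cells[[1L]]))
  body <- cells[-1L]
  if (length(body) == 0L)
    return(data.frame(table_name = character(), doc_file = character(),
                      data_file = character(), begin_year = integer(),
                      end_year = integer(), use_constraints = character(),
                      stringsAsFactors = FALSE))
  df <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  names(df) <- header
  df
}

#' Extract the three metadata collections from parsed documentation
#'
#' Turns a set of parsed documentation pages plus the release manifest into
#' the three metadata tables: table descriptions (one row per table, from the
#' manifest), variable metadata (one row per variable across all tables) and
#' the codebook (one row per possible value). Restricted tables contribute
#' metadata like any other: documentation is available for all data even when
#' the data themselves are not loaded.
#'
#' @param docs List of `codebook_doc` objects.
#' @param manifest A manifest from [parse_manifest()].
#' @return A list with elements `descriptions`, `variables`, `codebook`.
#' @export
extract_metadata <- function(docs, manifest) {
  tabs <- vapply(docs, function(d) d$table_name, character(1))
  missing <- setdiff(tabs, manifest$table_name)
  if (length(missing))
    stop("documentation for table(s) not in manifest: ",
         paste(missing, collapse = ", "))
  descr <- do.call(rbind, lapply(tabs, function(tn) {
    m <- manifest[manifest$table_name == tn, , drop = FALSE]
    questionnaire_description(
      table_name = tn, description = if ("description" %in% names(m))
        m$description[1L] else "",
      begin_year = m$begin_year[1L], end_year = m$end_year[1L],
      data_group = if ("data_group" %in% names(m)) m$data_group[1L] else "General",
      use_constraints = m$use_constraints[1L],
      doc_file = m$doc_file[1L], data_file = m$data_file[1L],
      date_published = if ("date_published" %in% names(m)) m$date_published[1L] else ""
    )
  }))
  if (is.null(descr)) descr <- empty_descriptions()
  var_rows <- unlist(lapply(docs, function(d)
    lapply(d$variables, `[[`, "var")), recursive = FALSE)
  vars <- if (length(var_rows)) do.call(rbind, var_rows) else empty_variables()
  cb_rows <- unlist(lapply(docs, function(d)
    lapply(d$variables, `[[`, "codebook")), recursive = FALSE)
  cb <- if (length(cb_rows)) do.call(rbind, cb_rows) else empty_codebook()
  rownames(descr) <- rownames(vars) <- rownames(cb) <- NULL
  list(descriptions = descr, variables = vars, codebook = cb)
}
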