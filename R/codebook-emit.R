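# HTML emitter for codebook documentation pages. The fixture generator uses
# this to produce pages in the dialect parse_doc_page() reads; the emit-parse
# identity is part of the test contract.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Emit a codebook documentation page as HTML
#'
#' Serialises a `codebook_doc` back to a documentation page in the dialect
#' that [parse_doc_page()] reads: one definition list per variable followed by
#' its value table. Skip targets equal to [skip_end_sentinel()] are printed as
#' "End of Section".
#'
#' @param doc A `codebook_doc` object.
#' @return A single HTML string.
#' @export
emit_doc_page <- function(doc) {
  out <- c(
    "<!DOCTYPE html>", "<html>", "<head>",
    paste0("<title>", html_escape(doc$table_name), "</title>"),
    "</head>", "<body>",
    paste0("<h1 id=\"table-name\">", html_escape(doc$table_name),
           ": Data Documentation and Codebook</h1>")
  )
  for (v in doc$variables) {
    var <- v$var
    out <- c(out, "<div class=\"variable\">",
             paste0("<h3 id=\"", html_escape(var$variable), "\">",
                    html_escape(var$variable), " - ",
                    html_escape(var$sas_label), "</h3>"),
             "<dl>")
    field <- function(label, value) {
      if (!nzchar(value)) return(character())
      paste0("<dt>", label, ":</dt><dd>", html_escape(value), "</dd>")
    }
    out <- c(out,
             field("Variable Name", var$variable),
             field("SAS Label", var$sas_label),
             field("English Text", var$english_text),
             field("English Instructions", var$english_instructions))
    for (t in var$target[[1L]]) out <- c(out, field("Target", t))
    out <- c(out, field("Hard Edits", var$hard_edits), "</dl>")
    cb <- v$codebook
    out <- c(out, "<table class=\"values\">",
             paste0("<tr>", paste0("<th>", .VALUE_HEADERS, "</th>",
                                   collapse = ""), "</tr>"))
    for (i in seq_len(nrow(cb))) {
      skip <- cb$skip_to_item[i]
      skip <- if (is.na(skip)) "" else if (skip == .SKIP_END) "End of Section" else skip
      cells <- c(cb$code_or_value[i], cb$value_description[i],
                 ifelse(is.na(cb$count[i]), "", format(cb$count[i])),
                 ifelse(is.na(cb$cumulative[i]), "", format(cb$cumulative[i])),
                 skip)
      out <- c(out, paste0("<tr>", paste0("<td>", html_escape(cells), "</td>",
                                          collapse = ""), "</tr>"))
    }
    out <- c(out, "</table>", "</div>")
  }
  out <- c(out, "</body>", "</html>")
  paste(out, collapse = "\n")
}

#' Emit a manifest as tab-separated text
#' @param manifest An `nhanes_manifest` data frame.
#' @return A single TSV string (with header).
#' @export
emit_manifest_tsv <- function(manifest) {
  cols <- c("table_name", "doc_file", "data_file", "begin_year", "end_year",
            "use_constraints")
  df <- as.data.frame(manifest)[, cols, drop = FALSE]
  lines <- c(paste(cols, collapse = "\t"),
             apply(df, 1L, function(r) paste(r, collapse = "\t")))
  paste(lines, collapse = "\n")
}

#' Construct a codebook document in memory
#'
#' Assembles a `codebook_doc` from variable records and codebook rows, in the
#' order given. Mostly used by the fixture generator and in tests; parsed
#' pages produce the same structure via [parse_doc_page()].
#'
#' @param table_name Table identifier.
#' @param variables List of `list(var = <questionnaire_variable row>,
#'   codebook = <codebook_rows data frame>)`.
#' @param source_path Optional provenance string.
#' @return An object of class `codebook_doc`.
#' @export
codebook_doc <- function(table_name, variables, source_path = "") {
  for (v in variables) {
    stopifnot(is.list(v), !is.null(v$var), !is.null(v$codebook))
    if (nrow(v$codebook) && any(v$codebook$variable != v$var$variable))
      stop("codebook rows for ", v$var$variable, " carry a different variable name")
  }
  structure(list(table_name = table_name, variables = variables,
                 source_path = source_path, parse_warnings = character()),
            class = "codebook_doc")
}
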