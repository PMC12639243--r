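# Reserved sentinels used throughout the package.
# - missing codes in codebooks are printed as "." (SAS convention)
# - end-of-section skip targets are normalised to a single sentinel so that
#   downstream skip-span logic never has to match free-text phrasings.
.MISSING_CODE <- "."
.SKIP_END <- "<End of Section>"
.RANGE_LABEL <- "Range of Values"

#' Sentinel used for end-of-section skip targets
#'
#' Codebook pages phrase "skip to the end of this questionnaire section" in
#' several ways. The parser normalises all of them to this single reserved
#' string so skip-graph code can test for it reliably.
#'
#' @return A length-one character string.
#' @export
skip_end_sentinel <- function() .SKIP_END

#' Sentinel code used for missing values in codebooks
#' @return A length-one character string (`"."`).
#' @export
missing_code_sentinel <- function() .MISSING_CODE

empty_descriptions <- function() {
  data.frame(
    table_name = character(), description = character(),
    begin_year = integer(), end_year = integer(),
    data_group = character(), use_constraints = character(),
    doc_file = character(), data_file = character(),
    date_published = character(), stringsAsFactors = FALSE
  )
}

empty_variables <- function() {
  out <- data.frame(
    variable = character(), table_name = character(),
    sas_label = character(), english_text = character(),
    english_instructions = character(), hard_edits = character(),
    stringsAsFactors = FALSE
  )
  out$target <- list()
  out
}

empty_codebook <- function() {
  data.frame(
    variable = character(), table_name = character(),
    code_or_value = character(), value_description = character(),
    count = integer(), cumulative = integer(),
    skip_to_item = character(), stringsAsFactors = FALSE
  )
}

#' Construct a one-row table description record
#'
#' One row of the QuestionnaireDescriptions metadata table: the per-release
#' bookkeeping for a single data table (cycle years, documentation and data
#' file locations, public/restricted status).
#'
#' @param table_name Table identifier, e.g. `"DEMO_B"`.
#' @param description Free-text description of the table.
#' @param begin_year,end_year First and last calendar year of the cycle.
#' @param data_group Data group label (e.g. `"Demographics"`).
#' @param use_constraints Either `"public"` or `"restricted"`.
#' @param doc_file,data_file Paths or URLs of the documentation page and the
#'   data file.
#' @param date_published Publication date (ISO string or `Date`).
#' @return A one-row data frame with the QuestionnaireDescriptions columns.
#' @export
questionnaire_description <- function(table_name, description = "",
                                      begin_year, end_year,
                                      data_group = "General",
                                      use_constraints = c("public", "restricted"),
                                      doc_file = "", data_file = "",
                                      date_published = "") {
  use_constraints <- match.arg(use_constraints)
  begin_year <- as.integer(begin_year)
  end_year <- as.integer(end_year)
  if (is.na(begin_year) || is.na(end_year) || begin_year > end_year)
    stop("begin_year must be <= end_year for table ", table_name)
  span <- end_year - begin_year
  if (!span %in% c(1L, 3L))
    warning("cycle span for ", table_name, " is ", span,
            " years; standard cycles span 1 (or 3 for pandemic-extended)")
  data.frame(
    table_name = as.character(table_name), description = as.character(description),
    begin_year = begin_year, end_year = end_year,
    data_group = as.character(data_group), use_constraints = use_constraints,
    doc_file = as.character(doc_file), data_file = as.character(data_file),
    date_published = as.character(date_published), stringsAsFactors = FALSE
  )
}

#' Construct a one-row variable metadata record
#'
#' One row of the QuestionnaireVariables metadata table. `target` is stored as
#' a list column because documentation pages may print one target line per
#' age/sex group; flattening them would lose information.
#'
#' @param variable Variable name (conventionally upper-case alphanumeric).
#' @param table_name Table the variable belongs to.
#' @param sas_label Short descriptive label.
#' @param english_text Full question/description text.
#' @param english_instructions,hard_edits Opaque documentation fields, kept
#'   verbatim.
#' @param target Character vector of target-population lines.
#' @return A one-row data frame with a `target` list column.
#' @export
questionnaire_variable <- function(variable, table_name, sas_label = "",
                                   english_text = "", english_instructions = "",
                                   hard_edits = "", target = character()) {
  variable <- as.character(variable)
  if (!nzchar(variable)) stop("variable name must be non-empty")
  if (!grepl("^[A-Z0-9_]+$", variable))
    warning("variable name ", sQuote(variable),
            " is not upper-case alphanumeric; keeping as-is")
  out <- data.frame(
    variable = variable, table_name = as.character(table_name),
    sas_label = as.character(sas_label), english_text = as.character(english_text),
    english_instructions = as.character(english_instructions),
    hard_edits = as.character(hard_edits), stringsAsFactors = FALSE
  )
  out$target <- list(as.character(target))
  out
}

#' Construct codebook rows for one variable
#'
#' Builds the VariableCodebook rows for a single variable: one row per
#' possible value, in document order. `cumulative` defaults to the running sum
#' of `count`.
#'
#' @param variable,table_name Identifiers of the enclosing variable block.
#' @param code_or_value Character vector: integer codes, a numeric range such
#'   as `"0 to 80"`, or the missing sentinel `"."`.
#' @param value_description English description of each code.
#' @param count Respondent counts per row (may be `NA` when the source page
#'   omits them).
#' @param cumulative Running totals; computed from `count` when omitted.
#' @param skip_to_item Skip target per row: a later variable name,
#'   [skip_end_sentinel()], or `NA` for no skip.
#' @return A data frame with the VariableCodebook columns.
#' @export
codebook_rows <- function(variable, table_name, code_or_value, value_description,
                          count = NA_integer_, cumulative = NULL,
                          skip_to_item = NA_character_) {
  n <- length(code_or_value)
  count <- rep_len(as.integer(count), n)
  if (is.null(cumulative))
    cumulative <- if (anyNA(count)) rep(NA_integer_, n) else cumsum(count)
  data.frame(
    variable = rep_len(as.character(variable), n),
    table_name = rep_len(as.character(table_name), n),
    code_or_value = as.character(code_or_value),
    value_description = as.character(value_description),
    count = count, cumulative = rep_len(as.integer(cumulative), n),
    skip_to_item = rep_len(as.character(skip_to_item), n),
    stringsAsFactors = FALSE
  )
}

#' Validate codebook rows
#'
#' Checks the structural invariants of a set of VariableCodebook rows: within
#' each (variable, table) group, codes are unique, `cumulative` is
#' nondecreasing in row order, and the final `cumulative` equals the sum of
#' `count` (when counts are present).
#'
#' @param cb A codebook data frame as produced by [codebook_rows()].
#' @return Invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_codebook <- function(cb) {
  if (nrow(cb) == 0L) return(invisible(TRUE))
  key <- paste(cb$table_name, cb$variable, sep = "\r")
  for (k in unique(key)) {
    g <- cb[key == k, , drop = FALSE]
    id <- paste0(g$variable[1L], " in ", g$table_name[1L])
    if (anyDuplicated(g$code_or_value))
      stop("duplicate codes for ", id, ": ",
           paste(unique(g$code_or_value[duplicated(g$code_or_value)]), collapse = ", "))
    cum <- g$cumulative
    if (!anyNA(cum)) {
      if (is.unsorted(cum)) stop("cumulative counts decrease for ", id)
      if (!anyNA(g$count) && cum[length(cum)] != sum(g$count))
        stop("last cumulative (", cum[length(cum)], ") != sum of counts (",
             sum(g$count), ") for ", id)
    }
  }
  invisible(TRUE)
}

collapse_target <- function(target) {
  vapply(target, function(x) paste(x, collapse = " | "), character(1))
}

split_target <- function(x) {
  lapply(strsplit(as.character(x), " | ", fixed = TRUE),
         function(v) v[nzchar(v)])
}

stop_missing_schema <- function(what) {
  stop(structure(
    class = c("nhanessnap_missing_schema", "error", "condition"),
    list(message = paste0("snapshot store has no ", what, " schema; build it first"),
         call = sys.call(-1), schema = what)
  ))
}

filter_tables <- function(df, table_names) {
  known <- unique(df$table_name)
  unknown <- setdiff(table_names, known)
  if (length(unknown))
    warning("unknown table name(s) in filter: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  df[df$table_name %in% table_names, , drop = FALSE]
}

#' List table descriptions held in a snapshot
#'
#' Returns the QuestionnaireDescriptions metadata. By default only tables with
#' public use constraints are returned; restricted tables are documented in
#' the metadata but their data are never loaded.
#'
#' @param store A [snapshot_store()].
#' @param include_restricted If `TRUE`, restricted-access tables are included.
#' @return A data frame of table descriptions.
#' @export
metadata_tab <- function(store, include_restricted = FALSE) {
  md <- store_metadata(store)
  out <- md$descriptions
  if (!include_restricted)
    out <- out[out$use_constraints == "public", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' List variable metadata held in a snapshot
#'
#' Returns the QuestionnaireVariables metadata, optionally restricted to a set
#' of tables. Rows are ordered by (table_name, variable) for stable output.
#'
#' @param store A [snapshot_store()].
#' @param table_names Optional character vector of table names to keep.
#'   Unknown names produce a warning and contribute no rows.
#' @return A data frame with one row per (table, variable).
#' @export
metadata_var <- function(store, table_names = NULL) {
  md <- store_metadata(store)
  out <- md$variables
  if (!is.null(table_names)) out <- filter_tables(out, table_names)
  out <- out[order(out$table_name, out$variable), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' List codebook entries held in a snapshot
#'
#' Returns the VariableCodebook metadata with conjunctive filtering on table
#' and variable names. Rows preserve codebook document order within each
#' variable (this order defines questionnaire order for skip logic).
#'
#' @param store A [snapshot_store()].
#' @param table_names Optional table filter (see [metadata_var()]).
#' @param variables Optional variable-name filter.
#' @return A data frame with one row per codebook value row.
#' @export
metadata_cb <- function(store, table_names = NULL, variables = NULL) {
  md <- store_metadata(store)
  out <- md$codebook
  if (!is.null(table_names)) out <- filter_tables(out, table_names)
  if (!is.null(variables)) out <- out[out$variable %in% variables, , drop = FALSE]
  rownames(out) <- NULL
  out
}
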