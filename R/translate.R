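is_range_code <- function(x) {
  grepl("^\\s*-?[0-9]+(\\.[0-9]+)?\\s+to\\s+-?[0-9]+(\\.[0-9]+)?\\s*$", x)
}

parse_range <- function(x) {
  parts <- strsplit(trimws(x), "\\s+to\\s+")[[1L]]
  as.numeric(parts)
}

is_missing_row <- function(cb) cb$code_or_value == .MISSING_CODE

#' Classify a variable from its codebook rows
#'
#' A variable is `continuous` when its only non-missing codebook row is a
#' value range ("X to Y"), `categorical` when all non-missing rows are
#' discrete codes, and `mixed` when a range coexists with discrete special
#' codes (refusal/don't-know style sentinels embedded in a numeric variable).
#'
#' @param entries Codebook rows for one (variable, table), from
#'   [codebook_rows()] or [metadata_cb()].
#' @return One of `"categorical"`, `"continuous"`, `"mixed"`.
#' @export
classify_variable <- function(entries) {
  if (nrow(entries) == 0L) stop("empty codebook; cannot classify")
  nonmiss <- entries[!is_missing_row(entries), , drop = FALSE]
  ranges <- is_range_code(nonmiss$code_or_value)
  if (sum(ranges) > 1L)
    stop("ambiguous codebook for ", entries$variable[1L],
         ": multiple value ranges (",
         paste(nonmiss$code_or_value[ranges], collapse = "; "), ")")
  if (sum(ranges) == 1L) {
    if (nrow(nonmiss) == 1L) "continuous" else "mixed"
  } else "categorical"
}

#' Translation policy
#'
#' Controls how special codes are handled when translating mixed variables.
#' By default any discrete code in a mixed variable whose description is not
#' "Range of Values" is treated as special and mapped to missing; the
#' occurrences are counted in the per-column report rather than silently
#' dropped.
#'
#' @param special_to What special codes become; only `NA` is supported.
#' @param range_label The description marking the in-range row.
#' @return A list of class `translation_policy`.
#' @export
translation_policy <- function(special_to = NA, range_label = .RANGE_LABEL) {
  structure(list(special_to = special_to, range_label = range_label),
            class = "translation_policy")
}

code_matches <- function(values, code) {
  num <- suppressWarnings(as.numeric(code))
  if (!is.na(num)) !is.na(values) & values == num
  else !is.na(values) & as.character(values) == code
}

#' Translate one raw column using its codebook
#'
#' Categorical columns have each code replaced by its value description
#' (plain character strings); unmapped codes become missing and are counted.
#' Continuous columns pass through numerically. Mixed columns keep in-range
#' numeric values and map special codes to missing per the policy.
#'
#' @param values Raw coded values (numeric or character).
#' @param entries Codebook rows for the column's variable.
#' @param policy A [translation_policy()].
#' @return A list with `values` (translated vector) and `report`
#'   (`kind`, `n_translated`, `n_special_to_missing`, `n_unmapped`).
#' @export
translate_column <- function(values, entries, policy = translation_policy()) {
  kind <- classify_variable(entries)
  report <- list(kind = kind, n_translated = 0L, n_special_to_missing = 0L,
                 n_unmapped = 0L)
  if (kind == "continuous") {
    report$n_translated <- sum(!is.na(values))
    return(list(values = values, report = report))
  }
  nonmiss <- entries[!is_missing_row(entries), , drop = FALSE]
  if (kind == "categorical") {
    out <- rep(NA_character_, length(values))
    mapped <- rep(FALSE, length(values))
    for (i in seq_len(nrow(nonmiss))) {
      hit <- code_matches(values, nonmiss$code_or_value[i])
      out[hit] <- nonmiss$value_description[i]
      mapped <- mapped | hit
    }
    unmapped <- !is.na(values) & !mapped
    report$n_unmapped <- sum(unmapped)
    report$n_translated <- sum(mapped)
    if (report$n_unmapped > 0L)
      warning(sum(unmapped), " unmapped code(s) for ",
              entries$variable[1L], " set to missing", call. = FALSE)
    return(list(values = out, report = report))
  }
  # mixed: numeric passthrough with special codes mapped to missing
  specials <- nonmiss[!is_range_code(nonmiss$code_or_value), , drop = FALSE]
  out <- values
  special_hit <- rep(FALSE, length(values))
  for (i in seq_len(nrow(specials)))
    special_hit <- special_hit | code_matches(values, specials$code_or_value[i])
  out[special_hit] <- policy$special_to
  report$n_special_to_missing <- sum(special_hit)
  report$n_translated <- sum(!is.na(values) & !special_hit)
  list(values = out, report = report)
}

#' Ordered factor levels for a categorical variable
#'
#' Returns the value descriptions of a categorical variable in codebook
#' document order, the order in which the source documentation lists them
#' (e.g. education levels from "Less than 9th grade" upwards). Missing-class
#' sentinel rows are excluded. Byte-identical duplicate labels are an error;
#' labels differing only in case pass here — detecting those is quality
#' control's job, not the data model's.
#'
#' @param entries Codebook rows for one categorical variable.
#' @return Character vector of labels, in document order.
#' @export
ordered_levels <- function(entries) {
  if (classify_variable(entries) != "categorical")
    stop("ordered_levels applies to categorical variables only")
  labels <- entries$value_description[!is_missing_row(entries)]
  dup <- unique(labels[duplicated(labels)])
  if (length(dup))
    stop("duplicate level label(s) for ", entries$variable[1L], ": ",
         paste(sQuote(dup), collapse = ", "))
  labels
}

#' Translate a raw table using its documentation
#'
#' Applies [translate_column()] to every column except `SEQN`, using the
#' table's parsed documentation page. Shape is preserved exactly: same rows,
#' same columns, `SEQN` untouched. Columns with no codebook block pass
#' through with a warning recorded in the report.
#'
#' @param raw Raw data frame; must contain a unique `SEQN` column.
#' @param doc The table's `codebook_doc`.
#' @param policy A [translation_policy()].
#' @return The translated data frame, with a `"translation"` attribute
#'   holding per-column reports and any warnings.
#' @export
translate_table <- function(raw, doc, policy = translation_policy()) {
  if (!"SEQN" %in% names(raw))
    stop("raw table ", doc$table_name, " has no SEQN column")
  if (anyDuplicated(raw$SEQN))
    stop("SEQN values are not unique in ", doc$table_name)
  out <- raw
  reports <- list()
  warnings <- character()
  for (col in setdiff(names(raw), "SEQN")) {
    cb <- doc_codebook(doc, col)
    if (is.null(cb) || nrow(cb) == 0L) {
      warnings <- c(warnings, paste0("no codebook block for column ", col,
                                     "; passed through untranslated"))
      reports[[col]] <- list(kind = "untranslated", n_translated = 0L,
                             n_special_to_missing = 0L, n_unmapped = 0L)
      next
    }
    tr <- translate_column(raw[[col]], cb, policy)
    out[[col]] <- tr$values
    reports[[col]] <- tr$report
  }
  attr(out, "translation") <- list(reports = reports, warnings = warnings)
  out
}
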