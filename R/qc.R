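#' Quality-control finding
#'
#' One detected cross-table inconsistency: the check that fired, the variable
#' concerned, the affected tables partitioned by variant, the per-variant
#' evidence, and a severity. Findings are evidence for human review, not
#' corrections: deciding whether two variants represent the same quantity is
#' deliberately left to curators.
#'
#' @param check_id One of `qc_check_ids()`.
#' @param variable Variable the finding concerns.
#' @param tables Named list partitioning the affected tables by variant.
#' @param evidence Per-variant values (named list), shaped per check.
#' @param severity `"info"`, `"warn"` or `"error"`.
#' @return An object of class `qc_finding`.
#' @export
qc_finding <- function(check_id, variable, tables, evidence,
                       severity = c("warn", "info", "error")) {
  severity <- match.arg(severity)
  stopifnot(check_id %in% qc_check_ids())
  structure(list(check_id = check_id, variable = variable, tables = tables,
                 evidence = evidence, severity = severity),
            class = "qc_finding")
}

#' Check identifiers known to the QC suite
#' @return Character vector of check ids.
#' @export
qc_check_ids <- function() {
  c("label_mismatch", "target_mismatch", "description_mismatch",
    "multi_table_in_cycle", "level_variant", "unit_change", "name_reuse",
    "presence_gap")
}

#' @export
print.qc_finding <- function(x, ...) {
  cat("<qc_finding> ", x$check_id, " [", x$severity, "] ", x$variable, "\n",
      sep = "")
  for (nm in names(x$tables))
    cat("  ", nm, ": ", paste(x$tables[[nm]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Flatten findings to a data frame
#' @param findings List of `qc_finding` objects.
#' @return A data frame with one row per finding.
#' @export
findings_table <- function(findings) {
  if (length(findings) == 0L)
    return(data.frame(check_id = character(), variable = character(),
                      severity = character(), tables = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(findings, function(f) data.frame(
    check_id = f$check_id, variable = f$variable, severity = f$severity,
    tables = paste(vapply(names(f$tables), function(nm)
      paste0(nm, "={", paste(f$tables[[nm]], collapse = ","), "}"),
      character(1)), collapse = " "),
    stringsAsFactors = FALSE)))
}

finding_ids <- function(findings) vapply(findings, `[[`, character(1), "check_id")

var_rows <- function(store, variable, scope = NULL) {
  md <- store_metadata(store)
  rows <- md$variables[md$variables$variable == variable, , drop = FALSE]
  if (!is.null(scope)) rows <- rows[rows$table_name %in% scope, , drop = FALSE]
  rows[order(rows$table_name), , drop = FALSE]
}

partition_by <- function(tables, values) {
  split(tables, values)
}

# Finding for one metadata field differing across tables.
field_finding <- function(check_id, variable, tables, values, severity = "warn") {
  groups <- partition_by(tables, values)
  if (length(groups) < 2L) return(NULL)
  qc_finding(check_id, variable, tables = groups,
             evidence = as.list(stats::setNames(names(groups), names(groups))),
             severity = severity)
}

#' Cross-table consistency check for one variable
#'
#' Tests the consistency of a variable's header metadata across every table
#' that carries it (all tables in the store by default): the SAS label, the
#' target population, and the English description, plus whether the variable
#' appears in more than one table within a single cycle. Comparison is
#' byte-exact and case-sensitive: seemingly innocuous changes in
#' capitalisation or abbreviation are exactly the hazards worth surfacing.
#'
#' @param store A built [snapshot_store()].
#' @param variable Variable name.
#' @param scope Optional set of table names restricting the check.
#' @return List of [qc_finding()] objects (possibly empty).
#' @export
qc_var <- function(store, variable, scope = NULL) {
  rows <- var_rows(store, variable, scope)
  if (nrow(rows) == 0L) {
    warning("variable ", variable, " not found",
            if (!is.null(scope)) " in scope", call. = FALSE)
    return(list())
  }
  findings <- list()
  add <- function(f) if (!is.null(f)) findings[[length(findings) + 1L]] <<- f
  add(field_finding("label_mismatch", variable, rows$table_name, rows$sas_label))
  add(field_finding("description_mismatch", variable, rows$table_name,
                    rows$english_text))
  add(field_finding("target_mismatch", variable, rows$table_name,
                    collapse_target(rows$target)))
  descr <- metadata_tab(store, include_restricted = TRUE)
  idx <- match(rows$table_name, descr$table_name)
  cycle <- paste0(descr$begin_year[idx], "-", descr$end_year[idx])
  multi <- split(rows$table_name, cycle)
  multi <- multi[lengths(multi) > 1L]
  if (length(multi))
    add(qc_finding("multi_table_in_cycle", variable, tables = multi,
                   evidence = multi, severity = "warn"))
  findings
}

normalize_label <- function(x) {
  x <- tolower(x)
  x <- gsub("\\s+", " ", x)
  x <- trimws(x)
  sub("[[:punct:]]+$", "", x)
}

levels_by_table <- function(store, variable, scope = NULL) {
  cb <- metadata_cb(store, variables = variable)
  if (!is.null(scope)) cb <- cb[cb$table_name %in% scope, , drop = FALSE]
  cb <- cb[!is_missing_row(cb) & !is_range_code(cb$code_or_value), , drop = FALSE]
  split(cb$value_description, cb$table_name)
}

#' Detect case/whitespace variants in categorical levels
#'
#' Collects each table's set of value descriptions for a categorical variable
#' and flags label pairs that are equal after case-folding, whitespace
#' collapsing and trailing-punctuation stripping, but not byte-equal. Such
#' variants silently split one category into two when tables are combined
#' into a factor. The finding partitions the affected tables by the variant
#' they use. Level sets that differ beyond normalisation are reported
#' separately at info severity (they may be genuine recodings).
#'
#' @inheritParams qc_var
#' @return List of [qc_finding()] objects.
#' @export
qc_levels <- function(store, variable, scope = NULL) {
  by_tab <- levels_by_table(store, variable, scope)
  if (length(by_tab) == 0L) return(list())
  findings <- list()
  long <- data.frame(
    table_name = rep(names(by_tab), lengths(by_tab)),
    label = unlist(by_tab, use.names = FALSE), stringsAsFactors = FALSE)
  long$norm <- normalize_label(long$label)
  for (nf in unique(long$norm)) {
    g <- long[long$norm == nf, , drop = FALSE]
    variants <- unique(g$label)
    if (length(variants) < 2L) next
    parts <- lapply(variants, function(v) sort(unique(g$table_name[g$label == v])))
    names(parts) <- variants
    findings[[length(findings) + 1L]] <- qc_finding(
      "level_variant", variable, tables = parts,
      evidence = as.list(stats::setNames(variants, variants)),
      severity = "warn")
  }
  # level sets differing beyond normalization: info-severity evidence only
  normsets <- lapply(by_tab, function(l) sort(unique(normalize_label(l))))
  sig <- vapply(normsets, paste, character(1), collapse = "\r")
  if (length(unique(sig)) > 1L) {
    groups <- split(names(by_tab), sig)
    names(groups) <- vapply(groups, function(t)
      paste(normsets[[t[1L]]], collapse = " / "), character(1))
    findings[[length(findings) + 1L]] <- qc_finding(
      "description_mismatch", variable, tables = groups,
      evidence = lapply(groups, function(t) normsets[[t[1L]]]),
      severity = "info")
  }
  findings
}

unit_tokens <- function(x) {
  m <- regmatches(x, gregexpr("\\(([^()]*)\\)", x))[[1L]]
  sort(unique(gsub("^\\(|\\)$", "", m)))
}

#' Detect unit changes for a variable across tables
#'
#' Two heuristics: (i) parenthesised unit tokens extracted from the SAS label
#' and English text differ across tables; (ii) the codebook value-range
#' midpoints differ across tables by at least `range_factor` (default 10x),
#' which catches unit changes that the labels fail to mention.
#'
#' @inheritParams qc_var
#' @param range_factor Multiplicative midpoint ratio at or above which ranges
#'   are considered incompatible.
#' @return List of [qc_finding()] objects.
#' @export
qc_units <- function(store, variable, scope = NULL, range_factor = 10) {
  rows <- var_rows(store, variable, scope)
  if (nrow(rows) < 2L) return(list())
  findings <- list()
  toks <- vapply(seq_len(nrow(rows)), function(i)
    paste(unit_tokens(paste(rows$sas_label[i], rows$english_text[i])),
          collapse = "; "), character(1))
  f <- field_finding("unit_change", variable, rows$table_name, toks)
  if (!is.null(f)) findings[[length(findings) + 1L]] <- f
  cb <- metadata_cb(store, table_names = rows$table_name, variables = variable)
  ranges <- cb[is_range_code(cb$code_or_value), , drop = FALSE]
  if (nrow(ranges) >= 2L) {
    mid <- vapply(ranges$code_or_value, function(r) mean(parse_range(r)),
                  numeric(1))
    pos <- mid[mid > 0]
    if (length(pos) >= 2L && max(pos) / min(pos) >= range_factor) {
      parts <- split(ranges$table_name, ranges$code_or_value)
      findings[[length(findings) + 1L]] <- qc_finding(
        "unit_change", variable, tables = parts,
        evidence = as.list(stats::setNames(unique(ranges$code_or_value),
                                           unique(ranges$code_or_value))),
        severity = "warn")
    }
  }
  findings
}

jaccard <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

text_tokens <- function(x) {
  toks <- strsplit(tolower(gsub("[^a-z0-9 ]", " ", tolower(x))), "\\s+")[[1L]]
  unique(toks[nzchar(toks)])
}

#' Detect reuse of one variable name for unrelated measurements
#'
#' The same variable name occasionally denotes two entirely different
#' measurements in different tables. English descriptions are compared by
#' token-set Jaccard similarity; a pair below the threshold triggers an
#' error-severity finding partitioning tables by description.
#'
#' @inheritParams qc_var
#' @param threshold Jaccard similarity below which descriptions are deemed
#'   unrelated (default 0.2).
#' @return List of [qc_finding()] objects.
#' @export
qc_name_reuse <- function(store, variable, threshold = 0.2, scope = NULL) {
  rows <- var_rows(store, variable, scope)
  if (nrow(rows) < 2L) return(list())
  texts <- unique(rows$english_text)
  if (length(texts) < 2L) return(list())
  toks <- lapply(texts, text_tokens)
  low <- FALSE
  for (i in seq_along(texts)) for (j in seq_len(i - 1L))
    if (jaccard(toks[[i]], toks[[j]]) < threshold) low <- TRUE
  if (!low) return(list())
  parts <- split(rows$table_name, rows$english_text)
  list(qc_finding("name_reuse", variable, tables = parts,
                  evidence = as.list(stats::setNames(names(parts), names(parts))),
                  severity = "error"))
}

#' Variable presence/absence matrix across tables
#'
#' Builds the variables-by-tables incidence matrix for a set of related
#' tables and flags every variable present in some but not all of them. The
#' canonical case is per-file renames of the same quantity (e.g. a
#' subsample weight named differently in each of three files): each rename
#' shows up as a variable absent from the other files. The matrix is
#' returned for manual review — deciding whether such variables represent
#' the same quantity requires a human.
#'
#' @param store A built [snapshot_store()].
#' @param tables Character vector of at least two table names.
#' @return A list with `matrix` (logical incidence, variables x tables) and
#'   `findings` (one `presence_gap` finding per partially present variable).
#' @export
qc_presence_matrix <- function(store, tables) {
  if (length(tables) < 2L) stop("need at least two tables")
  md <- metadata_var(store, table_names = tables)
  vars <- setdiff(sort(unique(md$variable)), "SEQN")
  m <- matrix(FALSE, nrow = length(vars), ncol = length(tables),
              dimnames = list(vars, tables))
  for (i in seq_len(nrow(md)))
    if (md$variable[i] %in% vars) m[md$variable[i], md$table_name[i]] <- TRUE
  findings <- list()
  for (v in vars) {
    present <- tables[m[v, ]]
    absent <- tables[!m[v, ]]
    if (length(absent) > 0L && length(present) > 0L)
      findings[[length(findings) + 1L]] <- qc_finding(
        "presence_gap", v,
        tables = list(present = present, absent = absent),
        evidence = list(absent = absent), severity = "warn")
  }
  list(matrix = m, findings = findings)
}

# Base name of a cyclic table family: DEMO_B -> DEMO.
table_base <- function(x) sub("_[A-Z]$", "", x)

#' Run every consistency check over a whole snapshot
#'
#' Sweeps all variables (except the join key `SEQN`) through [qc_var()],
#' [qc_levels()], [qc_units()] and [qc_name_reuse()], and runs
#' [qc_presence_matrix()] within each cyclic table family with at least two
#' member tables. A clean snapshot yields zero findings.
#'
#' @param store A built [snapshot_store()].
#' @return List of [qc_finding()] objects.
#' @export
qc_snapshot <- function(store) {
  md <- store_metadata(store)
  vars <- setdiff(sort(unique(md$variables$variable)), "SEQN")
  findings <- list()
  for (v in vars) {
    findings <- c(findings, qc_var(store, v), qc_levels(store, v),
                  qc_units(store, v), qc_name_reuse(store, v))
  }
  fams <- split(md$descriptions$table_name, table_base(md$descriptions$table_name))
  for (fam in fams)
    if (length(fam) >= 2L)
      findings <- c(findings, qc_presence_matrix(store, fam)$findings)
  findings
}
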