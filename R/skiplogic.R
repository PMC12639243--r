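#' Build the question-flow graph of a table
#'
#' Turns the "Skip to Item" entries of a table's codebook into a directed
#' skip graph over the table's variables in document order. Each codebook row
#' with a non-empty skip target contributes one edge (source variable,
#' triggering code, target). The target itself is still asked; the questions
#' strictly between source and target are the ones skipped. Targets that are
#' not in the document (cross-section jumps) or that point backwards are
#' recorded as anomalies, not edges.
#'
#' @param doc A `codebook_doc`.
#' @return A list of class `skip_graph` with `question_order`, `edges`
#'   (data frame: source, code, target) and `anomalies`.
#' @export
build_skip_graph <- function(doc) {
  order <- doc_variable_names(doc)
  pos <- stats::setNames(seq_along(order), order)
  edges <- anomalies <- data.frame(source = character(), code = character(),
                                   target = character(), reason = character(),
                                   stringsAsFactors = FALSE)
  for (v in doc$variables) {
    cb <- v$codebook
    if (nrow(cb) == 0L) next
    hit <- !is.na(cb$skip_to_item)
    for (i in which(hit)) {
      src <- v$var$variable
      tgt <- cb$skip_to_item[i]
      code <- cb$code_or_value[i]
      if (tgt == .SKIP_END) {
        edges <- rbind(edges, data.frame(source = src, code = code,
                                         target = tgt, reason = NA_character_,
                                         stringsAsFactors = FALSE))
      } else if (!tgt %in% order) {
        anomalies <- rbind(anomalies,
                           data.frame(source = src, code = code, target = tgt,
                                      reason = "target not in document",
                                      stringsAsFactors = FALSE))
      } else if (pos[[tgt]] <= pos[[src]]) {
        anomalies <- rbind(anomalies,
                           data.frame(source = src, code = code, target = tgt,
                                      reason = "backward target",
                                      stringsAsFactors = FALSE))
      } else {
        edges <- rbind(edges, data.frame(source = src, code = code,
                                         target = tgt, reason = NA_character_,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  edges$reason <- NULL
  structure(list(question_order = order, edges = edges, anomalies = anomalies),
            class = "skip_graph")
}

# Variables strictly between an edge's source and target in document order.
edge_span <- function(graph, source, target) {
  pos <- match(source, graph$question_order)
  end <- if (target == .SKIP_END) length(graph$question_order) + 1L
         else match(target, graph$question_order)
  if (end - pos < 2L) return(character())
  graph$question_order[(pos + 1L):(end - 1L)]
}

#' Identify questions that may have been skipped
#'
#' For each variable of a table, reports whether some upstream answer can
#' cause it to be skipped during administration, and if so which upstream
#' variables and codes trigger the skip. A variable V is skippable exactly
#' when an edge (U, c, T) has U before V and T after V (or T is the
#' end-of-section sentinel) in document order.
#'
#' @param doc A `codebook_doc`, or a prebuilt `skip_graph`.
#' @return A data frame with columns `variable`, `skippable` and a
#'   `skipped_by` list column (each element a named list mapping upstream
#'   variable to its triggering codes).
#' @export
get_skip_info <- function(doc) {
  graph <- if (inherits(doc, "skip_graph")) doc else build_skip_graph(doc)
  order <- graph$question_order
  spans <- lapply(seq_len(nrow(graph$edges)), function(i)
    edge_span(graph, graph$edges$source[i], graph$edges$target[i]))
  skipped_by <- lapply(order, function(v) {
    hits <- which(vapply(spans, function(s) v %in% s, logical(1)))
    if (length(hits) == 0L) return(list())
    by <- split(graph$edges$code[hits], graph$edges$source[hits])
    lapply(by, unique)
  })
  out <- data.frame(variable = order,
                    skippable = lengths(skipped_by) > 0L,
                    stringsAsFactors = FALSE)
  out$skipped_by <- skipped_by
  out
}

#' Simulate questionnaire administration for one respondent
#'
#' Walks the question order from the first variable. At each asked variable
#' the respondent's answer is consulted; if the answer triggers a skip edge,
#' administration jumps to the edge's target (or stops at end-of-section).
#' This is the brute-force ground truth against which the skip-span analysis
#' of [get_skip_info()] is verified.
#'
#' @param graph A `skip_graph`.
#' @param answers Named list or vector mapping variable name to the answered
#'   code (character or numeric).
#' @return Character vector of the variables asked, in administration order.
#' @export
simulate_administration <- function(graph, answers) {
  order <- graph$question_order
  edges <- graph$edges
  asked <- character()
  i <- 1L
  while (i <= length(order)) {
    v <- order[i]
    asked <- c(asked, v)
    if (!v %in% names(answers))
      stop("no answer provided for asked variable ", v)
    a <- answers[[v]]
    hit <- edges$source == v & vapply(edges$code, function(cd)
      isTRUE(code_matches(a, cd)), logical(1))
    if (any(hit)) {
      tgt <- edges$target[which(hit)[1L]]
      if (tgt == .SKIP_END) break
      i <- match(tgt, order)
    } else {
      i <- i + 1L
    }
  }
  asked
}

# Administration walk tolerant of missing answers: a missing answer never
# triggers a skip, the walk just continues. Used to classify missing cells.
walk_asked <- function(graph, answers) {
  order <- graph$question_order
  edges <- graph$edges
  asked <- rep(FALSE, length(order))
  i <- 1L
  while (i <= length(order)) {
    asked[i] <- TRUE
    v <- order[i]
    a <- answers[[v]]
    nxt <- i + 1L
    if (!is.null(a) && !is.na(a)) {
      hit <- edges$source == v & vapply(edges$code, function(cd)
        isTRUE(code_matches(a, cd)), logical(1))
      if (any(hit)) {
        tgt <- edges$target[which(hit)[1L]]
        if (tgt == .SKIP_END) break
        nxt <- match(tgt, order)
      }
    }
    i <- nxt
  }
  stats::setNames(asked, order)
}

#' Classify missing cells as structural or item nonresponse
#'
#' Survey skip rules record unasked questions as plain Missing, which is
#' misleading: a cell can be missing because the question was never asked
#' (structural) or because the respondent did not answer (item nonresponse).
#' A missing cell is classified `structurally_skipped` when one of the
#' respondent's observed upstream answers triggers a skip past the variable;
#' otherwise it is `item_nonresponse`. Respondents whose trigger answer is
#' itself missing are classified conservatively as item nonresponse.
#'
#' @param raw Raw coded data frame with `SEQN`.
#' @param doc The table's `codebook_doc`.
#' @return A data frame with `SEQN` plus one column per documented variable,
#'   each cell one of `"observed"`, `"structurally_skipped"`,
#'   `"item_nonresponse"`.
#' @export
classify_missing <- function(raw, doc) {
  graph <- build_skip_graph(doc)
  vars <- intersect(graph$question_order, names(raw))
  out <- data.frame(SEQN = raw$SEQN)
  for (v in vars) out[[v]] <- "observed"
  for (r in seq_len(nrow(raw))) {
    answers <- as.list(raw[r, vars, drop = FALSE])
    asked <- walk_asked(graph, answers)
    for (v in vars) {
      if (!is.na(answers[[v]])) next
      out[r, v] <- if (isTRUE(asked[[v]])) "item_nonresponse"
                   else "structurally_skipped"
    }
  }
  out
}

#' Right-censor a skipped question using a censoring source
#'
#' Some skipped questions are best treated as censored rather than missing:
#' e.g. when a respondent who never smoked is not asked the age at which they
#' started smoking, their current age is a right-censoring value for it. For
#' respondents whose upstream answer matches the trigger and whose value is
#' missing, the value is taken from the censoring source column with event
#' indicator 0; observed values keep their value with event 1; missing values
#' without the trigger stay missing with event `NA`.
#'
#' @param raw Raw data frame with `SEQN`.
#' @param variable Column to censor (e.g. the age-started-smoking question).
#' @param trigger List with `variable` (upstream question) and `codes`
#'   (answers that caused the skip).
#' @param censor_source Column supplying censoring values (e.g. current age).
#' @return A data frame `SEQN`, `value`, `event`, with a `"warnings"`
#'   attribute listing respondents whose censoring source was missing.
#' @export
right_censor <- function(raw, variable, trigger, censor_source) {
  for (col in c(variable, trigger$variable, censor_source))
    if (!col %in% names(raw)) stop("column ", col, " not present in raw table")
  y <- raw[[variable]]
  up <- raw[[trigger$variable]]
  src <- raw[[censor_source]]
  triggered <- rep(FALSE, length(up))
  for (cd in trigger$codes) triggered <- triggered | code_matches(up, cd)
  value <- y
  event <- ifelse(!is.na(y), 1L, NA_integer_)
  censor <- is.na(y) & triggered
  warnings <- character()
  no_src <- censor & is.na(src)
  if (any(no_src)) {
    warnings <- paste0("censoring source ", censor_source,
                       " missing for SEQN ", raw$SEQN[no_src],
                       "; cell left missing")
    censor <- censor & !is.na(src)
  }
  value[censor] <- src[censor]
  event[censor] <- 0L
  out <- data.frame(SEQN = raw$SEQN, value = value, event = event)
  attr(out, "warnings") <- warnings
  out
}
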