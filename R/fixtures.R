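# Synthetic multi-cycle release generator. Emits manifests, codebook HTML
# pages and coded raw tables that the parser, builder and QC suite consume;
# injections reproduce the classes of cross-cycle inconsistency seen in real
# releases, with ground truth recorded for recall testing.

fixture_var <- function(name, kind, sas_label, english_text,
                        target = "Both males and females 0 YEARS - 150 YEARS",
                        codes = NULL, labels = NULL, probs = NULL,
                        range = NULL, integer = FALSE, specials = NULL,
                        special_prob = NULL, skip = NULL, miss_prob = 0) {
  list(name = name, kind = kind, sas_label = sas_label,
       english_text = english_text, english_instructions = "",
       hard_edits = "", target = target, codes = as.character(codes),
       labels = labels, probs = probs, range = range, integer = integer,
       specials = specials, special_prob = special_prob, skip = skip,
       miss_prob = miss_prob)
}

default_fixture_tables <- function() {
  list(
    DEMO = list(name = "DEMO", data_group = "Demographics", restricted = FALSE,
      variables = list(
        fixture_var("RIAGENDR", "categorical", "Gender",
                    "Gender of the participant.",
                    codes = 1:2, labels = c("Male", "Female"),
                    probs = c(0.5, 0.5)),
        fixture_var("RIDAGEYR", "continuous", "Age in years at screening",
                    "Age in years of the participant at the time of screening.",
                    range = c(0, 80), integer = TRUE),
        fixture_var("DMDEDUC3", "categorical",
                    "Education Level - Children/Youth 6-19",
                    "What is the highest grade or level of school completed or the highest degree received.",
                    target = "Both males and females 6 YEARS - 19 YEARS",
                    codes = 1:5,
                    labels = c("Less Than 9th Grade", "9th Grade",
                               "10th Grade", "11th Grade",
                               "High School Graduate"),
                    probs = c(0.15, 0.2, 0.2, 0.2, 0.25), miss_prob = 0.05)
      )),
    SMQ = list(name = "SMQ", data_group = "Questionnaire", restricted = FALSE,
      variables = list(
        fixture_var("SMQ020", "categorical",
                    "Smoked at least 100 cigarettes in life",
                    "These next questions are about cigarette smoking. Have you smoked at least 100 cigarettes in your entire life.",
                    target = "Both males and females 18 YEARS - 150 YEARS",
                    codes = 1:2, labels = c("Yes", "No"), probs = c(0.45, 0.55),
                    skip = list(code = "2", target = "SMQ040"),
                    miss_prob = 0.04),
        fixture_var("SMD030", "continuous", "Age started smoking cigarettes regularly",
                    "How old were you when you first started to smoke cigarettes fairly regularly.",
                    target = "Both males and females 18 YEARS - 150 YEARS",
                    range = c(7, 76), integer = TRUE, miss_prob = 0.06),
        fixture_var("SMD057", "mixed", "Number of cigarettes smoked per day",
                    "How many cigarettes per day did you smoke when you last smoked regularly.",
                    target = "Both males and females 18 YEARS - 150 YEARS",
                    range = c(1, 95), integer = TRUE,
                    specials = c("777" = "Refused", "999" = "Don't know"),
                    special_prob = c(0.03, 0.02), miss_prob = 0.05),
        fixture_var("SMQ040", "categorical", "Do you now smoke cigarettes",
                    "Do you now smoke cigarettes.",
                    target = "Both males and females 18 YEARS - 150 YEARS",
                    codes = 1:3,
                    labels = c("Every day", "Some days", "Not at all"),
                    probs = c(0.4, 0.2, 0.4), miss_prob = 0.03)
      )),
    BMX = list(name = "BMX", data_group = "Examination", restricted = FALSE,
      variables = list(
        fixture_var("BMXBMI", "continuous", "Body Mass Index (kg/m**2)",
                    "Body Mass Index, calculated from height and weight.",
                    range = c(12, 70), miss_prob = 0.06)
      ))
  )
}

#' Specify a synthetic multi-cycle release
#'
#' Builds the specification the fixture generator consumes: the cycles, the
#' per-cycle table specs (identical across cycles until modified by
#' [inject()]), and the sample size. The defaults emulate a small release
#' with a demographic table, a smoking questionnaire with a skip rule, and a
#' body-measures table. Same spec plus same seed yields byte-identical
#' output.
#'
#' @param seed Integer seed driving all data generation.
#' @param n_cycles Number of 2-year cycles.
#' @param n_per_cycle Respondents per cycle.
#' @param begin_year First year of the first cycle.
#' @param tables Named list of table family specs; see
#'   `default_fixture_tables` in the package source for the shape.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_cycles = 2L, n_per_cycle = 60L,
                         begin_year = 1999L, tables = default_fixture_tables()) {
  stopifnot(n_cycles >= 1L, n_cycles <= 26L)
  cycles <- data.frame(
    index = seq_len(n_cycles),
    begin_year = begin_year + 2L * (seq_len(n_cycles) - 1L),
    end_year = begin_year + 2L * (seq_len(n_cycles) - 1L) + 1L,
    suffix = c("", paste0("_", LETTERS[seq_len(n_cycles)][-1L]))[seq_len(n_cycles)],
    stringsAsFactors = FALSE
  )
  resolved <- lapply(seq_len(n_cycles), function(i) tables)
  structure(list(seed = as.integer(seed), cycles = cycles,
                 n_per_cycle = as.integer(n_per_cycle),
                 resolved = resolved, injections = list()),
            class = "fixture_spec")
}

cycle_table_name <- function(base, suffix) paste0(base, suffix)

# Case-variant of a label: lower-case the first letter of its last word
# ("10th Grade" -> "10th grade"); if already lower, upper-case it.
variant_label <- function(label) {
  words <- strsplit(label, " ", fixed = TRUE)[[1L]]
  last <- words[length(words)]
  first <- substr(last, 1L, 1L)
  swapped <- if (first %in% LETTERS) tolower(first) else toupper(first)
  words[length(words)] <- paste0(swapped, substr(last, 2L, nchar(last)))
  paste(words, collapse = " ")
}

find_var <- function(tabspec, variable) {
  for (i in seq_along(tabspec$variables))
    if (tabspec$variables[[i]]$name == variable) return(i)
  NULL
}

#' Inject a cross-cycle inconsistency into a fixture spec
#'
#' Deterministically modifies the per-cycle table specs to emulate a known
#' hazard class, and records the ground truth so detection can be scored.
#' Supported `check_id`s and their parameters:
#'
#' * `level_variant`: `table`, `variable`, `level` (label), `from_cycle` —
#'   later cycles use a case-variant of the label.
#' * `unit_change`: `table`, `variable`, `factor` (default 100),
#'   `unit_from`, `unit_to`, `from_cycle` — later cycles scale the value
#'   range and swap the unit token in the SAS label.
#' * `name_reuse`: `table`, `variable`, `text`, `label`, `from_cycle` —
#'   later cycles describe an unrelated measurement under the same name.
#' * `label_mismatch`, `target_mismatch`, `description_mismatch`: `table`,
#'   `variable`, `value` (replacement text), `from_cycle`.
#' * `presence_gap`: `table`, `variables` (one name per cycle), `range` —
#'   each cycle's file carries its own uniquely named variable (the
#'   per-file subsample-weight rename pattern).
#' * `multi_table_in_cycle`: `variable`, `from_table`, `to_table`, `cycle` —
#'   the variable is duplicated into a second table of one cycle.
#'
#' @param spec A [fixture_spec()].
#' @param injection List with `check_id` plus parameters as above.
#' @return The modified spec (ground truth appended to `spec$injections`).
#' @export
inject <- function(spec, injection) {
  stopifnot(inherits(spec, "fixture_spec"), !is.null(injection$check_id))
  id <- injection$check_id
  if (!id %in% qc_check_ids()) stop("unknown check_id: ", id)
  n_cyc <- nrow(spec$cycles)
  from <- injection$from_cycle
  if (is.null(from)) from <- max(2L, ceiling(n_cyc / 2) + 1L)
  tname <- function(base, i) cycle_table_name(base, spec$cycles$suffix[i])
  truth <- list(check_id = id)

  if (id == "presence_gap") {
    base <- injection$table %||% "SSGLYP"
    varnames <- injection$variables
    stopifnot(length(varnames) == n_cyc)
    rng <- injection$range %||% c(0, 15)
    for (i in seq_len(n_cyc)) {
      tab <- spec$resolved[[i]][[base]]
      if (is.null(tab))
        tab <- list(name = base, data_group = "Laboratory", restricted = FALSE,
                    variables = list(
                      fixture_var("URXGLYP", "continuous",
                                  "Glyphosate (ng/mL)",
                                  "Glyphosate concentration in urine.",
                                  range = rng, miss_prob = 0.1)))
      tab$variables[[length(tab$variables) + 1L]] <-
        fixture_var(varnames[i], "continuous",
                    "Subsample weight (2 year)",
                    "Subsample examination weight for this file.",
                    range = c(1000, 90000))
      spec$resolved[[i]][[base]] <- tab
    }
    truth$variables <- varnames
    truth$tables <- vapply(seq_len(n_cyc), function(i) tname(base, i), character(1))
    spec$injections[[length(spec$injections) + 1L]] <- truth
    return(spec)
  }

  if (id == "multi_table_in_cycle") {
    i <- injection$cycle %||% 1L
    src <- spec$resolved[[i]][[injection$from_table]]
    dst <- spec$resolved[[i]][[injection$to_table]]
    vi <- find_var(src, injection$variable)
    if (is.null(vi)) stop("variable ", injection$variable, " not in ",
                          injection$from_table)
    dst$variables[[length(dst$variables) + 1L]] <- src$variables[[vi]]
    spec$resolved[[i]][[injection$to_table]] <- dst
    truth$variable <- injection$variable
    truth$tables <- c(tname(injection$from_table, i), tname(injection$to_table, i))
    spec$injections[[length(spec$injections) + 1L]] <- truth
    return(spec)
  }

  base <- injection$table
  variable <- injection$variable
  affected <- character()
  for (i in seq_len(n_cyc)) {
    if (i < from) next
    tab <- spec$resolved[[i]][[base]]
    vi <- find_var(tab, variable)
    if (is.null(vi)) stop("variable ", variable, " not in ", base)
    v <- tab$variables[[vi]]
    if (id == "level_variant") {
      level <- injection$level %||% v$labels[min(3L, length(v$labels))]
      li <- match(level, v$labels)
      if (is.na(li)) stop("level ", level, " not found for ", variable)
      v$labels[li] <- variant_label(level)
      truth$level <- level
      truth$variant <- v$labels[li]
    } else if (id == "unit_change") {
      fac <- injection$factor %||% 100
      v$range <- v$range * fac
      if (!is.null(injection$unit_from))
        v$sas_label <- sub(injection$unit_from, injection$unit_to,
                           v$sas_label, fixed = TRUE)
      truth$factor <- fac
    } else if (id == "name_reuse") {
      v$english_text <- injection$text %||%
        "Hexachlorobenzene concentration in serum specimen."
      if (!is.null(injection$label)) v$sas_label <- injection$label
    } else if (id == "label_mismatch") {
      v$sas_label <- injection$value %||% tolower(v$sas_label)
    } else if (id == "target_mismatch") {
      v$target <- injection$value %||%
        "Both males and females 12 YEARS - 150 YEARS"
    } else if (id == "description_mismatch") {
      v$english_text <- injection$value %||%
        paste(v$english_text, "Reported at the household interview.")
    } else {
      stop("injection for check_id ", id, " not supported")
    }
    tab$variables[[vi]] <- v
    spec$resolved[[i]][[base]] <- tab
    affected <- c(affected, tname(base, i))
  }
  truth$variable <- variable
  truth$tables_changed <- affected
  truth$tables_unchanged <- vapply(seq_len(from - 1L), function(i)
    tname(base, i), character(1))
  spec$injections[[length(spec$injections) + 1L]] <- truth
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- data + codebook generation -------------------------------------------

gen_values <- function(v, n) {
  if (v$kind == "categorical") {
    as.numeric(sample(v$codes, n, replace = TRUE,
                      prob = v$probs %||% rep(1, length(v$codes))))
  } else if (v$kind == "continuous") {
    x <- stats::runif(n, v$range[1L], v$range[2L])
    if (isTRUE(v$integer)) round(x) else round(x, 1)
  } else { # mixed
    x <- stats::runif(n, v$range[1L], v$range[2L])
    x <- if (isTRUE(v$integer)) round(x) else round(x, 1)
    if (!is.null(v$specials)) {
      u <- stats::runif(n)
      edges <- cumsum(v$special_prob)
      for (k in seq_along(v$specials)) {
        lo <- if (k == 1L) 0 else edges[k - 1L]
        x[u >= lo & u < edges[k]] <- as.numeric(names(v$specials)[k])
      }
    }
    x
  }
}

table_skip_edges <- function(tabspec) {
  out <- data.frame(source = character(), code = character(),
                    target = character(), stringsAsFactors = FALSE)
  for (v in tabspec$variables)
    if (!is.null(v$skip))
      out <- rbind(out, data.frame(source = v$name, code = v$skip$code,
                                   target = v$skip$target,
                                   stringsAsFactors = FALSE))
  out
}

# Apply skip rules: walk each respondent through the question order and blank
# cells for questions never asked.
apply_skips <- function(data, tabspec) {
  edges <- table_skip_edges(tabspec)
  if (nrow(edges) == 0L) return(data)
  order <- vapply(tabspec$variables, `[[`, character(1), "name")
  for (r in seq_len(nrow(data))) {
    i <- 1L
    asked <- rep(FALSE, length(order))
    while (i <= length(order)) {
      asked[i] <- TRUE
      a <- data[r, order[i]]
      nxt <- i + 1L
      if (!is.na(a)) {
        hit <- which(edges$source == order[i] &
                       vapply(edges$code, function(cd)
                         isTRUE(code_matches(a, cd)), logical(1)))
        if (length(hit)) {
          tgt <- edges$target[hit[1L]]
          if (tgt == .SKIP_END || !tgt %in% order) break
          nxt <- match(tgt, order)
        }
      }
      i <- nxt
    }
    if (any(!asked)) data[r, order[!asked]] <- NA
  }
  data
}

# Codebook rows for one variable, with counts taken from the realized data so
# that emitted documentation and emitted data always reconcile.
var_codebook <- function(v, table_name, values) {
  skip_for <- function(code) {
    if (!is.null(v$skip) && v$skip$code == code) {
      if (v$skip$target == "END") .SKIP_END else v$skip$target
    } else NA_character_
  }
  if (v$kind == "categorical") {
    counts <- vapply(v$codes, function(cd) sum(code_matches(values, cd)),
                     integer(1))
    codebook_rows(v$name, table_name,
                  code_or_value = c(v$codes, .MISSING_CODE),
                  value_description = c(v$labels, "Missing"),
                  count = c(counts, sum(is.na(values))),
                  skip_to_item = c(vapply(v$codes, skip_for, character(1)),
                                   NA_character_))
  } else if (v$kind == "continuous") {
    codebook_rows(v$name, table_name,
                  code_or_value = c(paste(v$range[1L], "to", v$range[2L]),
                                    .MISSING_CODE),
                  value_description = c(.RANGE_LABEL, "Missing"),
                  count = c(sum(!is.na(values)), sum(is.na(values))))
  } else {
    special_codes <- names(v$specials)
    n_special <- vapply(special_codes, function(cd)
      sum(code_matches(values, cd)), integer(1))
    in_range <- sum(!is.na(values)) - sum(n_special)
    codebook_rows(v$name, table_name,
                  code_or_value = c(paste(v$range[1L], "to", v$range[2L]),
                                    special_codes, .MISSING_CODE),
                  value_description = c(.RANGE_LABEL, unname(v$specials),
                                        "Missing"),
                  count = c(in_range, n_special, sum(is.na(values))))
  }
}

validate_fixture_spec <- function(spec) {
  for (i in seq_len(nrow(spec$cycles))) {
    for (tab in spec$resolved[[i]]) {
      order <- vapply(tab$variables, `[[`, character(1), "name")
      if (anyDuplicated(order))
        stop("duplicate variable names in table ", tab$name)
      for (v in tab$variables) {
        if (!is.null(v$skip) && v$skip$target != "END" &&
            !v$skip$target %in% order)
          stop("skip target ", v$skip$target, " of ", v$name,
               " is not defined in table ", tab$name)
        if (!is.null(v$skip) && v$skip$target %in% order &&
            match(v$skip$target, order) <= match(v$name, order))
          stop("skip target ", v$skip$target, " of ", v$name,
               " is not a later question")
      }
    }
  }
  invisible(TRUE)
}

#' Generate a synthetic release on disk
#'
#' Emits the full release tree for a spec: `manifest.tsv`, one codebook HTML
#' page per table under `docs/`, one coded data file per public table under
#' `data/` (CSV by default, SAS transport format when `format = "xpt"` and
#' the haven package is available), and `ground_truth.json` recording any
#' injected inconsistencies. Respondent identifiers (`SEQN`) are assigned
#' once per cycle and shared across that cycle's tables. Codebook counts are
#' computed from the realized data, so emitted documentation and data always
#' reconcile. The whole tree is a deterministic function of the spec and its
#' seed.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` (default) or `"xpt"`.
#' @return Invisibly, a list with `dir`, `manifest`, `docs` (named list of
#'   `codebook_doc`), `raw` (named list of data frames), `truth`.
#' @export
make_snapshot <- function(spec, dir, format = c("csv", "xpt")) {
  format <- match.arg(format)
  validate_fixture_spec(spec)
  if (format == "xpt" && !requireNamespace("haven", quietly = TRUE))
    stop("format = \"xpt\" requires the haven package")
  set.seed(spec$seed)
  dir.create(file.path(dir, "docs"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "data"), recursive = TRUE, showWarnings = FALSE)

  manifest <- NULL
  docs <- list()
  raw <- list()
  for (i in seq_len(nrow(spec$cycles))) {
    cyc <- spec$cycles[i, ]
    seqn <- (i - 1L) * 100000L + seq_len(spec$n_per_cycle)
    for (tab in spec$resolved[[i]]) {
      tn <- cycle_table_name(tab$name, cyc$suffix)
      data <- data.frame(SEQN = seqn)
      for (v in tab$variables) {
        vals <- gen_values(v, spec$n_per_cycle)
        if (v$miss_prob > 0)
          vals[stats::runif(spec$n_per_cycle) < v$miss_prob] <- NA
        data[[v$name]] <- vals
      }
      data <- apply_skips(data, tab)
      blocks <- lapply(tab$variables, function(v) list(
        var = questionnaire_variable(
          variable = v$name, table_name = tn, sas_label = v$sas_label,
          english_text = v$english_text,
          english_instructions = v$english_instructions,
          hard_edits = v$hard_edits, target = v$target),
        codebook = var_codebook(v, tn, data[[v$name]])
      ))
      doc <- codebook_doc(tn, blocks,
                          source_path = file.path("docs", paste0(tn, ".htm")))
      writeLines(emit_doc_page(doc), file.path(dir, "docs", paste0(tn, ".htm")))
      data_ext <- if (format == "xpt") ".xpt" else ".csv"
      data_file <- file.path("data", paste0(tn, data_ext))
      restricted <- isTRUE(tab$restricted)
      if (!restricted) {
        if (format == "xpt") haven::write_xpt(data, file.path(dir, data_file))
        else utils::write.csv(data, file.path(dir, data_file),
                              row.names = FALSE, na = "")
      }
      manifest <- rbind(manifest, data.frame(
        table_name = tn, doc_file = file.path("docs", paste0(tn, ".htm")),
        data_file = data_file, begin_year = cyc$begin_year,
        end_year = cyc$end_year, data_group = tab$data_group %||% "General",
        use_constraints = if (restricted) "restricted" else "public",
        stringsAsFactors = FALSE))
      docs[[tn]] <- doc
      if (!restricted) raw[[tn]] <- data
    }
  }
  class(manifest) <- c("nhanes_manifest", "data.frame")
  writeLines(emit_manifest_tsv(manifest), file.path(dir, "manifest.tsv"))
  jsonlite::write_json(spec$injections, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(list(dir = dir, manifest = manifest, docs = docs, raw = raw,
                 truth = spec$injections))
}

#' Generate per-cycle survey populations with known truth
#'
#' Emulates the respondent-level structure that design-based estimation
#' needs: per cycle, a stratified two-stage sample (strata containing PSUs
#' containing respondents) with lognormal sampling weights independent of the
#' outcome, an age variable defining the analysis domain (40-59), a binary
#' subgroup, and an outcome with a programmed linear drift in the true domain
#' mean across cycles plus between-PSU and residual variation. The true
#' domain mean per cycle is returned as ground truth.
#'
#' @param seed Integer seed.
#' @param n_cycles Number of cycles.
#' @param n_strata Strata per cycle.
#' @param psus_per_stratum PSUs per stratum.
#' @param n_per_psu Respondents per PSU.
#' @param base_mean True domain mean in the first cycle.
#' @param cycle_drift Additive drift in the true domain mean per cycle.
#' @param domain_shift Difference between domain and non-domain means.
#' @param psu_sd Between-PSU standard deviation.
#' @param resid_sd Residual standard deviation.
#' @param begin_year First year of the first cycle.
#' @return A list with `cycles` (named list of data frames with columns
#'   `SEQN`, `RIDAGEYR`, `RIAGENDR`, `WTMEC2YR`, `SDMVSTRA`, `SDMVPSU`,
#'   `BMXBMI`), `truth` (data frame `cycle`, `true_mean`), and the design
#'   parameters.
#' @export
make_survey_population <- function(seed = 1L, n_cycles = 3L, n_strata = 3L,
                                   psus_per_stratum = 6L, n_per_psu = 25L,
                                   base_mean = 25, cycle_drift = 0.6,
                                   domain_shift = 2, psu_sd = 0.5,
                                   resid_sd = 4.5, begin_year = 1999L) {
  if (psus_per_stratum < 2L)
    warning("strata with fewer than 2 PSUs break the between-PSU variance",
            " formula (lonely PSU)")
  set.seed(seed)
  cycles <- list()
  truth <- NULL
  for (i in seq_len(n_cycles)) {
    n <- n_strata * psus_per_stratum * n_per_psu
    stratum <- rep(seq_len(n_strata), each = psus_per_stratum * n_per_psu)
    psu <- rep(rep(seq_len(psus_per_stratum), each = n_per_psu), n_strata)
    age <- sample(20:79, n, replace = TRUE)
    sex <- sample(1:2, n, replace = TRUE)
    in_domain <- age >= 40 & age <= 59
    psu_eff <- stats::rnorm(n_strata * psus_per_stratum, 0, psu_sd)
    idx <- (stratum - 1L) * psus_per_stratum + psu
    mu <- base_mean + cycle_drift * (i - 1L) - domain_shift * (1 - in_domain)
    y <- mu + psu_eff[idx] + stats::rnorm(n, 0, resid_sd)
    w <- stats::rlnorm(n, log(10000), 0.4)
    cyc <- paste0(begin_year + 2L * (i - 1L), "-", begin_year + 2L * (i - 1L) + 1L)
    cycles[[cyc]] <- data.frame(
      SEQN = (i - 1L) * 100000L + seq_len(n), RIDAGEYR = age, RIAGENDR = sex,
      WTMEC2YR = w, SDMVSTRA = stratum, SDMVPSU = psu, BMXBMI = round(y, 1))
    truth <- rbind(truth, data.frame(
      cycle = cyc, true_mean = base_mean + cycle_drift * (i - 1L),
      stringsAsFactors = FALSE))
  }
  list(cycles = cycles, truth = truth,
       params = list(seed = seed, n_strata = n_strata,
                     psus_per_stratum = psus_per_stratum,
                     n_per_psu = n_per_psu, psu_sd = psu_sd,
                     resid_sd = resid_sd))
}

#' Build a snapshot store from generated survey populations
#'
#' Splits each cycle's population into a demographic table (design columns)
#' and a body-measures table (outcome), registered in the raw namespace with
#' minimal table descriptions, ready for [cycle_series()].
#'
#' @param pop Output of [make_survey_population()].
#' @param container_version,collection_date Version stamp for the store.
#' @return A [snapshot_store()].
#' @export
population_store <- function(pop, container_version = "fixture",
                             collection_date = Sys.Date()) {
  store <- snapshot_store()
  descr <- NULL
  suffixes <- c("", paste0("_", LETTERS[-1L]))
  for (i in seq_along(pop$cycles)) {
    df <- pop$cycles[[i]]
    years <- as.integer(strsplit(names(pop$cycles)[i], "-")[[1L]])
    demo <- cycle_table_name("DEMO", suffixes[i])
    bmx <- cycle_table_name("BMX", suffixes[i])
    store_put_table(store, demo,
                    df[, c("SEQN", "RIDAGEYR", "RIAGENDR", "WTMEC2YR",
                           "SDMVSTRA", "SDMVPSU")], "raw")
    store_put_table(store, bmx, df[, c("SEQN", "BMXBMI")], "raw")
    descr <- rbind(descr,
                   questionnaire_description(demo, "Demographics",
                                             years[1L], years[2L]),
                   questionnaire_description(bmx, "Body Measures",
                                             years[1L], years[2L]))
  }
  store$metadata <- list(descriptions = descr, variables = empty_variables(),
                         codebook = empty_codebook())
  write_version_info(store, container_version, collection_date)
  store
}
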