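# Shared builders for the test suite. Everything is generated in code; no
# fixture files are stored.

# One release built once per test run and shared read-only across files.
.test_cache <- new.env(parent = emptyenv())

default_release <- function() {
  if (is.null(.test_cache$release)) {
    dir <- file.path(tempdir(), "nhanessnap-default-release")
    unlink(dir, recursive = TRUE)
    res <- make_snapshot(fixture_spec(seed = 101L, n_cycles = 2L), dir)
    store <- build_snapshot_from_dir(dir, container_version = "t0",
                                     collection_date = "2024-01-15")
    .test_cache$release <- list(dir = dir, res = res, store = store)
  }
  .test_cache$release
}

# A smoking-questionnaire doc with the canonical one-edge skip pattern:
# answering No (2) to the gateway question skips the age-started question.
smoking_doc <- function() {
  v1 <- questionnaire_variable("SMQ020", "SMQ", "Smoked at least 100 cigarettes in life",
                               "Have you smoked at least 100 cigarettes in your entire life.")
  cb1 <- codebook_rows("SMQ020", "SMQ", c("1", "2", "."),
                       c("Yes", "No", "Missing"), count = c(4L, 5L, 1L),
                       skip_to_item = c(NA, "SMQ040", NA))
  v2 <- questionnaire_variable("SMD030", "SMQ", "Age started smoking cigarettes regularly",
                               "How old were you when you started smoking regularly.")
  cb2 <- codebook_rows("SMD030", "SMQ", c("7 to 76", "."),
                       c("Range of Values", "Missing"), count = c(3L, 7L))
  v3 <- questionnaire_variable("SMQ040", "SMQ", "Do you now smoke cigarettes",
                               "Do you now smoke cigarettes.")
  cb3 <- codebook_rows("SMQ040", "SMQ", c("1", "2", "."),
                       c("Yes", "No", "Missing"), count = c(3L, 5L, 2L))
  codebook_doc("SMQ", list(list(var = v1, codebook = cb1),
                           list(var = v2, codebook = cb2),
                           list(var = v3, codebook = cb3)))
}

# Random forward-skip questionnaire doc for property tests: n_vars
# categorical questions, each with 2-3 codes, some carrying a forward skip.
random_skip_doc <- function(seed, n_vars = 6L, p_edge = 0.4) {
  set.seed(seed)
  vars <- sprintf("Q%02d", seq_len(n_vars))
  blocks <- vector("list", n_vars)
  for (i in seq_len(n_vars)) {
    k <- sample(2:3, 1L)
    codes <- as.character(seq_len(k))
    skip <- rep(NA_character_, k)
    if (i < n_vars && stats::runif(1) < p_edge) {
      ci <- sample(k, 1L)
      # forward target strictly after i; allow the end sentinel
      choices <- c(vars[seq(i + 1L, n_vars)], skip_end_sentinel())
      skip[ci] <- sample(choices, 1L)
    }
    v <- questionnaire_variable(vars[i], "QX", paste("Question", i),
                                paste("Text of question", i))
    cb <- codebook_rows(vars[i], "QX", c(codes, "."),
                        c(paste("Answer", codes), "Missing"),
                        count = rep(1L, k + 1L),
                        skip_to_item = c(skip, NA))
    blocks[[i]] <- list(var = v, codebook = cb)
  }
  codebook_doc("QX", blocks)
}

doc_codes <- function(doc) {
  out <- lapply(doc$variables, function(v) {
    cb <- v$codebook
    codes <- cb$code_or_value[cb$code_or_value != missing_code_sentinel() &
                                !grepl(" to ", cb$code_or_value)]
    # continuous variables have no discrete codes; any in-range answer will
    # do (it can never match a skip-triggering code)
    if (length(codes) == 0L) codes <- "<value>"
    codes
  })
  names(out) <- vapply(doc$variables, function(v) v$var$variable, character(1))
  out
}

# Exhaustively enumerate every answer vector over the doc's codebook codes and
# derive the skippable set from administration simulation alone.
skippable_by_enumeration <- function(doc) {
  graph <- build_skip_graph(doc)
  codes <- doc_codes(doc)
  grid <- expand.grid(codes, stringsAsFactors = FALSE)
  names(grid) <- names(codes)
  never <- character()
  all_vars <- graph$question_order
  not_asked <- rep(FALSE, length(all_vars))
  names(not_asked) <- all_vars
  for (r in seq_len(nrow(grid))) {
    asked <- simulate_administration(graph, as.list(grid[r, , drop = FALSE]))
    not_asked[setdiff(all_vars, asked)] <- TRUE
  }
  names(not_asked)[not_asked]
}

# Independent variance oracle: stratified PSU bootstrap (Rao-Wu-Yue rescaled,
# n_h - 1 resamples per stratum), recomputing the weighted mean per replicate
# from per-PSU totals. Shares no code with linearized_variance().
boot_se_oracle <- function(value, weight, stratum, psu, domain = NULL,
                           reps = 10000L, seed = 1L) {
  set.seed(seed)
  if (is.null(domain)) domain <- rep(TRUE, length(value))
  domain <- domain & !is.na(value)
  id <- paste(stratum, psu, sep = "/")
  wy <- rowsum(ifelse(domain, weight * value, 0), id)
  w <- rowsum(ifelse(domain, weight, 0), id)
  st <- sub("/.*$", "", rownames(wy))
  means <- numeric(reps)
  num <- matrix(0, nrow = reps, ncol = 1)
  den <- matrix(0, nrow = reps, ncol = 1)
  for (h in unique(st)) {
    rows <- which(st == h)
    nh <- length(rows)
    m <- nh - 1L
    pick <- matrix(sample(rows, m * reps, replace = TRUE), ncol = reps)
    num <- num + (nh / m) * colSums(matrix(wy[pick], ncol = reps))
    den <- den + (nh / m) * colSums(matrix(w[pick], ncol = reps))
  }
  stats::sd(num / den)
}

# Random stratified two-stage design with respondent-level data.
random_design_data <- function(seed) {
  set.seed(seed)
  n_strata <- sample(2:4, 1L)
  psus <- sample(4:8, 1L)
  per_psu <- sample(8:20, 1L)
  n <- n_strata * psus * per_psu
  stratum <- rep(seq_len(n_strata), each = psus * per_psu)
  psu <- rep(rep(seq_len(psus), each = per_psu), n_strata)
  psu_eff <- stats::rnorm(n_strata * psus, 0, 0.6)
  idx <- (stratum - 1L) * psus + psu
  list(value = 20 + psu_eff[idx] + stats::rnorm(n, 0, 3),
       weight = stats::rlnorm(n, log(5000), 0.5),
       stratum = stratum, psu = psu,
       domain = stats::runif(n) < 0.6)
}

# Random injection drawn from the full hazard catalogue, with matching
# expected check_id.
random_injection <- function(id, n_cycles) {
  later <- seq(2L, max(2L, n_cycles))
  from <- later[sample.int(length(later), 1L)]
  switch(id,
    level_variant = list(check_id = id, table = "DEMO", variable = "DMDEDUC3",
                         from_cycle = from),
    unit_change = list(check_id = id, table = "BMX", variable = "BMXBMI",
                       factor = 100, unit_from = "(kg/m**2)",
                       unit_to = "(g/cm**2)", from_cycle = from),
    name_reuse = list(check_id = id, table = "SMQ", variable = "SMD030",
                      text = "Hematocrit percentage of whole blood specimen.",
                      from_cycle = from),
    label_mismatch = list(check_id = id, table = "DEMO", variable = "RIAGENDR",
                          from_cycle = from),
    target_mismatch = list(check_id = id, table = "SMQ", variable = "SMQ040",
                           from_cycle = from),
    description_mismatch = list(check_id = id, table = "DEMO",
                                variable = "RIDAGEYR", from_cycle = from),
    presence_gap = list(check_id = id, table = "SSGLYP",
                        variables = sprintf("WTSS%s2Y",
                                            LETTERS[seq_len(n_cycles)])),
    multi_table_in_cycle = list(check_id = id, variable = "RIAGENDR",
                                from_table = "DEMO", to_table = "BMX",
                                cycle = 1L)
  )
}
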