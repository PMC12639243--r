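#' Specify a complex survey design
#'
#' Bundles one cycle's respondent-level design information: sampling weight,
#' stratum, primary sampling unit (PSU, the first-stage cluster, treated as
#' nested within stratum), the analysis variable, and a domain (subgroup)
#' indicator. Domain estimation keeps the full design: out-of-domain
#' respondents are retained so that between-PSU variance is computed
#' correctly, and their residuals are zeroed rather than their rows dropped.
#' Rows with a missing analysis value are treated as out of domain
#' (complete-case within subgroup).
#'
#' @param value Numeric analysis variable.
#' @param weight Positive sampling weights.
#' @param stratum Stratum identifiers.
#' @param psu PSU identifiers, nested within stratum.
#' @param domain Logical subgroup membership (default: everyone).
#' @return An object of class `survey_design`.
#' @export
survey_design <- function(value, weight, stratum, psu, domain = NULL) {
  n <- length(value)
  if (is.null(domain)) domain <- rep(TRUE, n)
  stopifnot(length(weight) == n, length(stratum) == n, length(psu) == n,
            length(domain) == n)
  if (any(is.na(weight)) || any(weight <= 0))
    stop("sampling weights must be positive and non-missing")
  domain <- domain & !is.na(value)
  structure(list(value = as.numeric(value), weight = as.numeric(weight),
                 stratum = as.character(stratum),
                 psu = paste(stratum, psu, sep = "\r"),
                 domain = as.logical(domain)),
            class = "survey_design")
}

#' Design-weighted (Hajek) mean
#'
#' The ratio estimator `sum(w * y) / sum(w)` over in-domain respondents: the
#' standard design-based mean, invariant to rescaling all weights by a
#' positive constant.
#'
#' @param design A [survey_design()].
#' @return The weighted mean (numeric scalar).
#' @export
weighted_mean_design <- function(design) {
  d <- design$domain
  if (!any(d)) stop("no in-domain respondents")
  sum(design$weight[d] * design$value[d]) / sum(design$weight[d])
}

#' Taylor-linearized variance of the design-weighted mean
#'
#' Stratified with-replacement first-stage (PSU) Taylor linearization, the
#' standard approach for public-use two-stage survey data. Residuals
#' `z_i = d_i * w_i * (y_i - mean) / sum(w d)` are totalled per PSU; the
#' variance is `sum_h n_h/(n_h - 1) * sum_j (Z_hj - Zbar_h)^2` over strata,
#' with all PSUs of the full design retained (out-of-domain units contribute
#' zero residual). Degrees of freedom follow the usual survey convention:
#' number of PSUs minus number of strata.
#'
#' @param design A [survey_design()].
#' @param lonely_psu Policy for strata with a single PSU: `"fail"` (default)
#'   or `"centre"` (deviation taken from the grand mean of PSU totals, one
#'   term, no inflation factor).
#' @return A list with `se`, `variance` and `df`.
#' @export
linearized_variance <- function(design, lonely_psu = c("fail", "centre")) {
  lonely_psu <- match.arg(lonely_psu)
  d <- design$domain
  if (!any(d)) stop("no in-domain respondents")
  mu <- weighted_mean_design(design)
  W <- sum(design$weight[d])
  z <- ifelse(d, design$weight * (design$value - mu), 0) / W
  psu_tot <- tapply(z, design$psu, sum)
  psu_stratum <- sub("\r.*$", "", names(psu_tot))
  strata <- unique(psu_stratum)
  v <- 0
  grand <- mean(psu_tot)
  for (h in strata) {
    Zh <- psu_tot[psu_stratum == h]
    nh <- length(Zh)
    if (nh < 2L) {
      if (lonely_psu == "fail")
        stop("stratum ", h, " has a single PSU; set lonely_psu = \"centre\"",
             " or collapse strata")
      v <- v + (Zh - grand)^2
    } else {
      v <- v + nh / (nh - 1) * sum((Zh - mean(Zh))^2)
    }
  }
  v <- as.numeric(v)
  list(se = sqrt(v), variance = v,
       df = length(psu_tot) - length(strata))
}

#' Design-based mean with confidence interval
#'
#' Combines [weighted_mean_design()] and [linearized_variance()] into an
#' estimate with a t-based confidence interval on `df = PSUs - strata`
#' degrees of freedom.
#'
#' @param design A [survey_design()].
#' @param level Confidence level in (0, 1).
#' @param lonely_psu Passed to [linearized_variance()].
#' @return An object of class `svy_estimate`: list with `mean`, `se`,
#'   `ci_low`, `ci_high`, `df`, `level`, `n_effective` (in-domain count).
#' @export
svy_estimate <- function(design, level = 0.95, lonely_psu = "fail") {
  stopifnot(level > 0, level < 1)
  mu <- weighted_mean_design(design)
  lv <- linearized_variance(design, lonely_psu = lonely_psu)
  if (lv$df <= 0L) stop("nonpositive design degrees of freedom (",
                        lv$df, "); too few PSUs")
  tq <- stats::qt(1 - (1 - level) / 2, df = lv$df)
  structure(list(mean = mu, se = lv$se,
                 ci_low = mu - tq * lv$se, ci_high = mu + tq * lv$se,
                 df = lv$df, level = level,
                 n_effective = sum(design$domain)),
            class = "svy_estimate")
}

#' @export
print.svy_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("mean %.*f  SE %.*f  %g%% CI [%.*f, %.*f]  df %d  n %d\n",
              digits, x$mean, digits, x$se, 100 * x$level,
              digits, x$ci_low, digits, x$ci_high, x$df, x$n_effective))
  invisible(x)
}

#' Stratified PSU bootstrap standard error
#'
#' Rao-Wu-Yue rescaled bootstrap: within each stratum, `n_h - 1` PSUs are
#' resampled with replacement and rescaled by `n_h / (n_h - 1)`; the
#' design-weighted mean is recomputed per replicate and its standard
#' deviation across replicates estimates the standard error. Serves as an
#' independent check on the linearization.
#'
#' @param design A [survey_design()].
#' @param reps Number of bootstrap replicates.
#' @param seed Optional RNG seed for reproducibility.
#' @return The bootstrap standard error (numeric scalar).
#' @export
bootstrap_se <- function(design, reps = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- design$domain
  swy <- tapply(ifelse(d, design$weight * design$value, 0), design$psu, sum)
  sw <- tapply(ifelse(d, design$weight, 0), design$psu, sum)
  psu_stratum <- sub("\r.*$", "", names(swy))
  strata <- unique(psu_stratum)
  num <- den <- numeric(reps)
  for (h in strata) {
    idx <- which(psu_stratum == h)
    nh <- length(idx)
    if (nh < 2L) { # lonely PSU: no resampling variability from this stratum
      num <- num + swy[idx]
      den <- den + sw[idx]
      next
    }
    m <- nh - 1L
    draws <- matrix(sample(idx, m * reps, replace = TRUE), nrow = m)
    scale <- nh / m
    num <- num + scale * colSums(matrix(swy[draws], nrow = m))
    den <- den + scale * colSums(matrix(sw[draws], nrow = m))
  }
  stats::sd(num / den)
}

#' Per-cycle design-based estimates across a snapshot
#'
#' Reproduces the canonical cross-cycle analysis: for each cycle, join the
#' analysis table to the demographic table on `SEQN`, restrict to a domain,
#' and compute the design-based mean with confidence interval using that
#' cycle's weights, strata and PSUs. Each cycle is analysed independently;
#' cycles are never pooled (see [pooled_analysis_guard()]).
#'
#' @param store A built [snapshot_store()].
#' @param value Variable to analyse (e.g. `"BMXBMI"`).
#' @param value_table Table family carrying `value` (base name, e.g. `"BMX"`).
#' @param design_table Table family carrying the design columns (e.g.
#'   `"DEMO"`); may equal `value_table`.
#' @param weight,stratum,psu Design column names. `weight` may instead be a
#'   named character vector mapping table name to that table's weight column
#'   when the weight variable is named differently per file; without such a
#'   mapping a missing weight column is an error naming the cycle.
#' @param domain Function of the joined data frame returning a logical
#'   domain indicator; default keeps everyone.
#' @param level Confidence level.
#' @param cycles Optional subset of cycle labels ("begin-end").
#' @return A data frame with one row per cycle: `cycle`, `table`, `mean`,
#'   `se`, `ci_low`, `ci_high`, `df`, `n`.
#' @export
cycle_series <- function(store, value, value_table, design_table = value_table,
                         weight = "WTMEC2YR", stratum = "SDMVSTRA",
                         psu = "SDMVPSU", domain = NULL, level = 0.95,
                         cycles = NULL) {
  descr <- metadata_tab(store)
  fam <- descr[table_base(descr$table_name) == value_table, , drop = FALSE]
  fam <- fam[order(fam$begin_year), , drop = FALSE]
  fam$cycle <- paste0(fam$begin_year, "-", fam$end_year)
  if (!is.null(cycles)) fam <- fam[fam$cycle %in% cycles, , drop = FALSE]
  if (nrow(fam) == 0L) stop("no tables found for family ", value_table)
  out <- NULL
  for (i in seq_len(nrow(fam))) {
    vt <- fam$table_name[i]
    cyc <- fam$cycle[i]
    df <- store_get_table(store, vt, "raw")
    if (design_table != value_table) {
      suffix <- sub(paste0("^", value_table), "", vt)
      dt <- paste0(design_table, suffix)
      df <- merge(df, store_get_table(store, dt, "raw"), by = "SEQN")
    }
    wcol <- if (length(weight) > 1L || !is.null(names(weight))) {
      if (!vt %in% names(weight))
        stop("no weight mapping for table ", vt, " (cycle ", cyc, ")")
      weight[[vt]]
    } else weight
    for (col in c(wcol, stratum, psu))
      if (!col %in% names(df))
        stop("cycle ", cyc, ": required design column ", col,
             " not found in table ", vt)
    dom <- if (is.null(domain)) rep(TRUE, nrow(df)) else domain(df)
    des <- survey_design(value = df[[value]], weight = df[[wcol]],
                         stratum = df[[stratum]], psu = df[[psu]],
                         domain = dom)
    est <- svy_estimate(des, level = level)
    out <- rbind(out, data.frame(
      cycle = cyc, table = vt, mean = est$mean, se = est$se,
      ci_low = est$ci_low, ci_high = est$ci_high, df = est$df,
      n = est$n_effective, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Guard against naive pooling of cycles
#'
#' Pooling respondents across cycles requires care: a secular trend in the
#' estimand makes a common pooled mean ill-defined, and sampling weights
#' reference each cycle's own population, which may have changed. This guard
#' emits a warning restating both cautions and performs no pooled estimate;
#' acknowledging it records the request but still does not pool.
#'
#' @param cycles Cycle labels the user asked to pool.
#' @param weight_specs Optional weight specification per cycle (recorded).
#' @param acknowledge Set when the caller has read the caution; the warning
#'   is still logged in the returned record.
#' @return A record list with `pooled = FALSE`, the cycles, and the message.
#' @export
pooled_analysis_guard <- function(cycles, weight_specs = NULL,
                                  acknowledge = FALSE) {
  msg <- paste0(
    "pooling ", length(cycles), " cycles requested: pooled estimates are not",
    " computed. A secular trend across cycles makes a common pooled mean",
    " ill-defined, and sampling weights are derived relative to each cycle's",
    " reference population, which may differ; consult the survey sponsor's",
    " guidance before combining weights.")
  record <- list(pooled = FALSE, cycles = cycles,
                 weight_specs = weight_specs, message = msg,
                 acknowledged = acknowledge)
  if (length(cycles) > 1L && !acknowledge)
    warning(structure(class = c("nhanessnap_pooling_warning", "warning",
                                "condition"),
                      list(message = msg, call = sys.call(-1))))
  record
}
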