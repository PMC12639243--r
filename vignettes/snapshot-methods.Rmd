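---
title: "Methods: snapshot stores, skip logic, cross-cycle QC and design-based estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: snapshot stores, skip logic, cross-cycle QC and design-based estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nhanessnap)
```

This vignette is the package's own account of how each component works, which
choices were genuinely open, and what the test evidence does and does not
establish.

## The snapshot model

A release of an NHANES-style survey is a set of per-cycle data tables, each
with an HTML documentation page, listed in a manifest. `nhanessnap` loads one
release into a **snapshot store** with three namespaces:

* **raw** — the data exactly as distributed, never altered;
* **translated** — the same tables with categorical codes replaced by their
  codebook value descriptions (plain character strings; ordered-factor
  conversion is an explicit, separate step via `ordered_levels()` plus
  `factor()`, because imposing factor semantics silently is how level-variant
  bugs become invisible);
* **metadata** — three tables derived from the documentation:
  one row per table (`QuestionnaireDescriptions`), one row per variable
  across all tables (`QuestionnaireVariables`), one row per possible value
  (`VariableCodebook`) — plus the two-field `VersionInfo` record.

The store is versioned: `VersionInfo` holds a container version and a single
collection date for the whole snapshot (no per-table dates; a snapshot is one
synchronisation event). Writing it twice requires an explicit overwrite.
Restricted-access tables contribute metadata and documentation but no data,
so their documentation remains searchable. The in-memory backend is an
environment-backed registry persisted as a directory of plain-text files;
the registry API is the contract, and a relational backend can sit behind it
unchanged.

Two design rules worth stating explicitly:

* **Identifiers are compared case-sensitively** throughout the data model.
  Case-insensitive comparison is the *QC layer's* job — folding case in the
  model would destroy exactly the evidence `qc_levels()` exists to find.
* `target` on a variable is stored as a list of lines, because documentation
  pages may print one target line per age/sex group; flattening would lose
  information. Two documentation fields (`EnglishInstructions`, `HardEdits`)
  are carried as opaque strings with no semantics attached.

## Codebook parsing

`parse_doc_page()` reads a documented dialect: variable blocks are definition
lists carrying a "Variable Name" field ("SAS Label", "English Text",
"English Instructions", "Target", "Hard Edits" are recognised), and the value
table is identified by its "Code or Value" header row with columns
"Value Description", "Count", "Cumulative", "Skip to Item". Unknown field
labels are recorded as parse warnings, never dropped silently. Counts
tolerate thousands separators; an absent Count column yields missing counts,
not zeros. End-of-section skip phrasings are normalised to a single sentinel
(`skip_end_sentinel()`). A page with no recognisable variable block raises a
structured unsupported-dialect error carrying a byte offset; the snapshot
builder responds by excluding that table and logging it, since real releases
contain a handful of files whose documentation is not in the standard format.

Document order is load-bearing: the order of variable blocks defines
questionnaire order, which is what skip-logic analysis runs on.

## Translation

`classify_variable()` calls a variable *continuous* when its only non-missing
codebook row is a value range ("X to Y"), *categorical* when all non-missing
rows are discrete codes, and *mixed* when a range coexists with discrete
codes. Two distinct ranges are an error (an ambiguous codebook, not a data
problem to paper over). For mixed variables the special-code vocabulary is
policy-driven with one documented default: any discrete code whose
description is not "Range of Values" is special and maps to missing, counted
in the per-column report (`n_special_to_missing`). Unmapped categorical codes
become missing with a warning rather than an error: decades-long releases
guarantee stragglers, and QC — not a crashed build — is where they should
surface. Translation preserves shape exactly and never touches `SEQN`.

## Skip logic and structural missingness

The "Skip to Item" column induces a directed graph over a table's variables:
one edge per codebook row with a skip target. Semantics: the target is the
next question *asked*, so the questions skipped are those strictly between
source and target in document order. Backward targets and targets outside
the document are recorded as anomalies, not edges — the upstream format does
not document them, and guessing would corrupt the span logic.

`get_skip_info()` derives skippability analytically (V is skippable iff some
edge jumps from before V to after V); `simulate_administration()` is the
brute-force ground truth, walking the question order and jumping as answers
trigger edges. The two are verified against each other by exhaustive
enumeration of all answer vectors on generated questionnaires of up to 8
variables with 2–3 codes each — small enough to enumerate completely, large
enough to contain chained and overlapping skips.

`classify_missing()` calls a missing cell *structurally skipped* when one of
the respondent's observed upstream answers triggers an edge past it, else
*item nonresponse*. A respondent whose trigger answer is itself missing is
classified conservatively as item nonresponse: claiming structure we cannot
observe would understate nonresponse. `right_censor()` implements the
standard reinterpretation of one such pattern — respondents routed past an
age-at-onset question get their current age as a right-censoring value with
event indicator 0. The package prepares (value, event) pairs only; survival
modelling belongs to dedicated packages.

## Cross-cycle quality control

All checks operate on metadata, return evidence, and correct nothing:
deciding whether two variants denote the same quantity is curation, and the
findings are designed to be handed to humans.

* `qc_var()` — byte-exact comparison of SAS label, English text and target
  across the tables carrying a variable, plus a check for a variable
  appearing in more than one table within a cycle. This deliberately matches
  the four documented dimensions and nothing more; the further checks are
  separate operations rather than silently folded in.
* `qc_levels()` — labels equal after case-folding, whitespace collapsing and
  trailing-punctuation stripping but not byte-equal are *level variants*,
  with the affected tables partitioned by variant. Nothing stronger
  (stemming, edit distance) is applied: every finding must be explainable by
  pointing at the two strings. Level sets differing beyond normalisation are
  reported separately at info severity — they may be genuine recodings.
* `qc_units()` — two heuristics: parenthesised unit tokens from the labels,
  and codebook range midpoints differing by ≥ 10× (configurable). The ratio
  default is a decade because unit changes in practice are decimal
  (µg/L ↔ nmol/L style); a smaller factor would start flagging ordinary
  range revisions.
* `qc_name_reuse()` — token-set Jaccard similarity of English descriptions
  below 0.2 (configurable) flags the same name used for unrelated
  measurements, at error severity. 0.2 separates paraphrase (which shares
  most content words) from unrelated text (which shares none) with a wide
  margin on both sides.
* `qc_presence_matrix()` — the variables × tables incidence matrix over a
  set of related files, flagging variables present in some but not all. This
  is the check that catches per-file renames of the same quantity (e.g. a
  subsample weight named differently in each of three files); the matrix is
  returned because the decision that they *are* the same quantity is manual.

Severity levels (info/warn/error) are this package's own ranking, chosen so
that error is reserved for findings that would silently corrupt an analysis
(name reuse), warn for findings that change results detectably, and info for
evidence without a verdict.

## Design-based estimation

The estimator is the Hájek ratio mean over the domain with Taylor-linearized
variance under the stratified, with-replacement first-stage (PSU) model —
the standard treatment for public-use two-stage survey data, where
within-PSU sampling details are not released. The formula choice (rather
than, say, replicate weights) was open; linearization was chosen because it
needs nothing beyond the released design columns and has a clean independent
check. Conventions, each configurable or documented:

* **Domain estimation keeps the full design**: out-of-domain respondents are
  retained with zero residual. Subsetting rows first would treat the domain
  sample as the design and understate the variance.
* Missing analysis values are treated as out of domain (complete-case within
  subgroup), recorded via `n_effective`.
* **df = #PSU − #strata**, the common survey convention.
* **Lonely PSUs** (single-PSU strata) fail by default; `lonely_psu =
  "centre"` deviates that PSU from the grand mean of PSU totals instead.
  Failing is the default because centring is a bias trade-off the analyst
  should opt into knowingly.
* PSU identifiers are treated as nested within stratum (the released
  convention, where PSU "1" recurs in every stratum).

`bootstrap_se()` and the test-suite oracle implement the Rao–Wu–Yue rescaled
bootstrap (resample `n_h − 1` PSUs per stratum with replacement, rescale by
`n_h/(n_h − 1)`), which is exactly variance-matched to the linearization for
totals; for the nonlinear ratio the two differ by `O(1/#PSU)`, so agreement
is asserted at 5% relative error on designs with 2–4 strata, 4–8 PSUs per
stratum and 8–20 respondents per PSU, with 10,000 replicates (bootstrap
Monte Carlo error ≈ 0.7% at that size). On the smallest such designs the
observed maximum over 20 designs sits near that 5% bound — that is the
expected finite-PSU behaviour of the two estimators, not noise to be
averaged away.

`cycle_series()` analyses each cycle independently — join on `SEQN`, restrict
to the domain, estimate. Pooling cycles is refused by design:
`pooled_analysis_guard()` warns that a secular trend makes a common pooled
mean ill-defined and that weights reference each cycle's own population, and
computes nothing. Weight variables renamed per file must be mapped explicitly
per table; guessing a weight column is the one mistake this module must
never make, since every inference depends on it.

## The fixture generator

`make_snapshot()` emits complete synthetic releases: manifest, codebook HTML
pages, coded data files (CSV by default; SAS transport via haven behind a
flag), with `SEQN` assigned once per cycle and shared across that cycle's
tables. The generator and the rest of the package are tested against each
other in both directions: emitted pages must re-parse identically, emitted
codebook counts are computed from the realized data (so count reconciliation
holds by construction and any drift is a translator bug), and clean
snapshots must produce zero QC findings for any seed. `inject()` produces
the hazard classes deterministically — case-variant levels split across a
cycle boundary, a 100× range scaling with a unit-token swap, an unrelated
description under a reused name, per-file weight renames, a variable
duplicated within a cycle — and records ground truth for recall scoring.

Default study conditions, chosen once: 2-year cycles from 1999; 60
respondents per cycle in the default release (enough for every categorical
level and both skip branches to realise, small enough to keep 50-snapshot QC
sweeps fast); a smoking questionnaire whose gateway question skips two
downstream questions (the canonical one-edge pattern plus a mixed-type
variable inside the skip span); item-nonresponse rates of 3–8% per variable.
Survey populations default to 3 strata × 6 PSUs × 25 respondents per cycle
(df = 15), between-PSU SD 0.5 and residual SD 4.5 around a domain mean of
25 drifting by 0.6 per cycle — magnitudes typical of an adult BMI series —
with lognormal weights independent of the outcome, which is what makes the
programmed domain mean the estimand.

What the generator does *not* emulate, and therefore what green tests do not
show: real documentation markup variation beyond the documented dialect,
informative sampling (weights correlated with outcomes), nonresponse that is
not missing-completely-at-random, cross-table skip targets, and realistic
marginal distributions of real variables. Structural fidelity, not
distributional fidelity, is the design goal.

## Numerical and degenerate-input choices

* Codebook `cumulative` must be nondecreasing with final value equal to the
  sum of counts; validation failures are errors, not warnings.
* Zero between-PSU variance yields SE exactly 0 and a degenerate interval at
  the mean (no artificial floor).
* Weighted-mean and variance are invariant to rescaling all weights by a
  positive constant (asserted as a property test).
* Empty domains, missing `SEQN`, duplicate codes, two-range codebooks, and
  nonpositive df all fail fast with named errors.
* Ties in `qc_levels()` partitioning are impossible by construction (tables
  are partitioned by exact byte variant).

## Problem sizes used by the test suite

The suite runs entirely on generated data: exhaustive skip enumeration on
docs of ≤ 8 variables; 50 seeded snapshots (2–3 cycles, 30 respondents per
cycle) for QC recall and false positives; 20 random designs × 10,000
bootstrap replicates and 1,000 coverage replicates for the estimation
checks. These sizes were chosen to make the checks exhaustive (skip logic),
or to put Monte Carlo error well inside the asserted tolerances (estimation),
while keeping the default test run in tens of seconds.

## Known limitations

* The documentation dialect is the documented minimum; real-page adapters
  for two decades of markup drift would subclass the parser.
* No pooled multi-cycle estimator, no regression/GLM machinery, and no
  replicate-weight (BRR/jackknife) variance in this version.
* QC findings are evidence, not corrections; no automatic harmonisation.
* The HTTP layer is an interface only; the shipped provider reads local
  release directories.
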