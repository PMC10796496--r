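# Documented patient-level CSV schema: column -> allowed range (NULL = any
# finite numeric). Binaries are explicit 0/1 integers; no strings.
.cohort_schema <- list(
  id                 = NULL,
  arm                = c(0, 1),
  age                = c(0, 120),
  sex                = c(0, 1),
  nihss              = c(0, 42),
  aspects            = c(0, 10),
  hmca               = c(0, 1),
  af_ecg             = c(0, 1),
  glucose            = c(0.5, 60),
  prestroke_mrs      = c(0, 6),
  onset_to_treatment = c(0, 1440),
  sht                = c(0, 1),
  any_ht             = c(0, 1),
  mrs90              = c(0, 6),
  ffo                = c(0, 1)
)

#' Patient-level cohort CSV schema
#'
#' Returns the documented column set for patient-level cohort tables: opaque
#' `id`; `arm` (1 = active treatment, 0 = control); on-admission covariates
#' `age` (years), `sex`, `nihss` (0-42), `aspects` (0-10), `hmca` (hyperdense
#' middle cerebral artery sign), `af_ecg` (atrial fibrillation on ECG),
#' `glucose` (mmol/L), `prestroke_mrs` (0-6), `onset_to_treatment` (minutes);
#' and outcomes `sht` (symptomatic hemorrhagic transformation), `any_ht`,
#' `mrs90` (day-90 modified Rankin Scale, 0-6) and `ffo` (favorable
#' functional outcome, mRS <= 2). All binaries are coded 0/1.
#'
#' @return Character vector of column names.
#' @export
cohort_schema <- function() names(.cohort_schema)

#' Validate a patient-level cohort table
#'
#' Checks every column present against its documented range and enforces the
#' logical record invariants: `sht = 1` implies `any_ht = 1`, and
#' `ffo = 1` exactly when `mrs90 <= 2`. Violations are reported with the
#' offending row and field. Missing values are permitted but flagged.
#'
#' @param cohort Data frame using the [cohort_schema()] column names.
#' @param require_all Require every schema column to be present.
#' @return The validated cohort, invisibly, with an `"n_missing"` attribute
#'   giving the count of missing values per column.
#' @export
validate_cohort <- function(cohort, require_all = FALSE) {
  stopifnot(is.data.frame(cohort))
  if (require_all) {
    miss <- setdiff(names(.cohort_schema), names(cohort))
    if (length(miss))
      stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  for (col in intersect(names(cohort), names(.cohort_schema))) {
    rng <- .cohort_schema[[col]]
    if (is.null(rng)) next
    v <- cohort[[col]]
    if (!is.numeric(v))
      stop("column '", col, "' must be numeric")
    bad <- which(!is.na(v) & (v < rng[1] | v > rng[2]))
    if (length(bad))
      stop("out-of-range value in field '", col, "' at row ", bad[1],
           " (value ", v[bad[1]], ", allowed ", rng[1], "-", rng[2], ")")
    int_cols <- c("arm", "sex", "nihss", "aspects", "hmca", "af_ecg",
                  "prestroke_mrs", "sht", "any_ht", "mrs90", "ffo")
    if (col %in% int_cols) {
      bad <- which(!is.na(v) & v != round(v))
      if (length(bad))
        stop("non-integer value in field '", col, "' at row ", bad[1])
    }
  }
  if (all(c("sht", "any_ht") %in% names(cohort))) {
    bad <- which(!is.na(cohort$sht) & !is.na(cohort$any_ht) &
                   cohort$sht == 1 & cohort$any_ht == 0)
    if (length(bad))
      stop("record invariant violated at row ", bad[1],
           ": sht = 1 requires any_ht = 1")
  }
  if (all(c("ffo", "mrs90") %in% names(cohort))) {
    bad <- which(!is.na(cohort$ffo) & !is.na(cohort$mrs90) &
                   cohort$ffo != as.integer(cohort$mrs90 <= 2))
    if (length(bad))
      stop("record invariant violated at row ", bad[1],
           ": ffo must equal 1 exactly when mrs90 <= 2")
  }
  nm <- vapply(cohort, function(v) sum(is.na(v)), integer(1))
  if (any(nm > 0))
    message("cohort contains missing values in: ",
            paste(names(nm)[nm > 0], collapse = ", "))
  attr(cohort, "n_missing") <- nm
  invisible(cohort)
}

#' Read a patient-level cohort from CSV
#'
#' Reads and validates a CSV file following [cohort_schema()]. Row order is
#' preserved; validation errors name the offending row and field.
#'
#' @param path Path to a CSV file with a header row.
#' @param require_all Require the full schema (default `TRUE`).
#' @return A validated data frame of patient records.
#' @export
read_cohort <- function(path, require_all = TRUE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(d, require_all = require_all)
  d
}

#' Write a patient-level cohort to CSV
#'
#' @param cohort Data frame of patient records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Group a cohort by risk score and arm
#'
#' Collapses unit records to a grouped cohort: one cell per (score value,
#' arm) with the cell size `n` and the event count of each binary outcome.
#' Grouping then expanding with [expand_cohort()] is lossless for binary
#' outcomes.
#'
#' @param cohort Data frame with an `arm` column and the outcome columns.
#' @param score Integer score per record (e.g. the HTI score), or the name of
#'   a column of `cohort`.
#' @param outcomes Character vector of binary outcome columns to tally.
#' @return A `grouped_cohort` data frame with columns `score`, `arm`, `n` and
#'   one event-count column per outcome.
#' @export
group_cohort <- function(cohort, score,
                         outcomes = intersect(c("sht", "any_ht", "ffo"),
                                              names(cohort))) {
  if (is.character(score) && length(score) == 1) {
    stopifnot(score %in% names(cohort))
    score <- cohort[[score]]
  }
  stopifnot(length(score) == nrow(cohort), !anyNA(score))
  key <- interaction(score, cohort$arm, drop = TRUE)
  out <- data.frame(
    score = as.integer(tapply(score, key, function(v) v[1])),
    arm   = as.integer(tapply(cohort$arm, key, function(v) v[1])),
    n     = as.integer(tapply(score, key, length))
  )
  for (o in outcomes)
    out[[o]] <- as.integer(tapply(cohort[[o]], key, sum))
  out <- out[order(out$score, -out$arm), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, outcomes = outcomes, class = c("grouped_cohort", "data.frame"))
}

#' Expand a grouped cohort to unit records
#'
#' Inverse of [group_cohort()]: each cell becomes `n` unit rows; for each
#' outcome the first `events` rows of the cell are events. Because events are
#' assigned from the top of each cell, nested outcomes (symptomatic HT within
#' any HT) keep their hierarchy whenever the counts do.
#'
#' @param grouped A `grouped_cohort`.
#' @param score_name Column name for the score in the expanded table.
#' @return Data frame of unit records with `score_name`, `arm` and one 0/1
#'   column per outcome.
#' @export
expand_cohort <- function(grouped, score_name = "hti") {
  outcomes <- attr(grouped, "outcomes")
  rows <- lapply(seq_len(nrow(grouped)), function(i) {
    n <- grouped$n[i]
    if (n == 0) return(NULL)
    cell <- data.frame(score = rep(grouped$score[i], n),
                       arm = rep(grouped$arm[i], n))
    for (o in outcomes) {
      e <- grouped[[o]][i]
      if (is.na(e)) e <- 0L
      cell[[o]] <- rep(c(1L, 0L), c(e, n - e))
    }
    cell
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- score_name
  rownames(out) <- NULL
  out
}

#' Grouped two-arm stroke cohort reconstructed from published tables
#'
#' Deterministic fixture: the 238-patient middle-cerebral-artery stroke
#' cohort of the CEREHETIS randomized thrombolysis trial (91 treated with
#' Cerebrolysin, 147 controls), grouped by arm and HTI score (0-4), with the
#' published event counts for symptomatic hemorrhagic transformation, any
#' hemorrhagic transformation, and favorable functional outcome per cell.
#' Per-cell sizes are 34/34/17/6/0 (treated) and 67/37/30/11/2 (control) at
#' HTI 0-4. Individual mRS values are not recoverable from the published
#' stratum medians, so the fixture carries binary outcomes only.
#'
#' @return A `grouped_cohort` (see [group_cohort()]).
#' @export
cerehetis_cohort <- function() {
  g <- data.frame(
    score  = rep(0:4, each = 2),
    arm    = rep(c(1L, 0L), 5),
    n      = c(34L, 67L, 34L, 37L, 17L, 30L, 6L, 11L, 0L, 2L),
    sht    = c(0L, 2L, 0L, 4L, 1L, 7L, 2L, 3L, 0L, 1L),
    any_ht = c(2L, 5L, 6L, 11L, 4L, 13L, 3L, 7L, 0L, 1L),
    ffo    = c(32L, 58L, 24L, 23L, 10L, 15L, 3L, 1L, 0L, 1L)
  )
  structure(g, outcomes = c("sht", "any_ht", "ffo"),
            class = c("grouped_cohort", "data.frame"))
}

#' Pearson chi-square test for a 2x2 table
#'
#' One-degree-of-freedom Pearson chi-square without continuity correction,
#' the test used for arm-wise comparisons of binary endpoints. Cells are
#' (events, non-events) for each arm.
#'
#' @param a,b Treated events and non-events.
#' @param c,d Control events and non-events.
#' @return List with `chi2`, `df` (= 1) and `p` (upper-tail).
#' @export
contingency_test <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin: both rows and both columns must have positive totals")
  ct <- stats::chisq.test(m, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = 1L, p = unname(ct$p.value))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples. By default the p-value uses
#' the normal approximation with tie correction (and no continuity
#' correction); `exact = TRUE` switches to the exact distribution, suitable
#' for tiny tie-free samples.
#'
#' @param x,y Numeric samples, both nonempty.
#' @param exact Use the exact null distribution (no ties allowed).
#' @return List with `U` (number of (x, y) pairs with x > y, ties half) and
#'   `p`.
#' @export
mann_whitney <- function(x, y, exact = FALSE) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  list(U = unname(wt$statistic), p = unname(wt$p.value))
}

#' @export
print.grouped_cohort <- function(x, ...) {
  cat("Grouped cohort:", sum(x$n), "subjects,",
      length(unique(x$score)), "score strata, outcomes:",
      paste(attr(x, "outcomes"), collapse = ", "), "\n")
  print(as.data.frame(x), ...)
  invisible(x)
}
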