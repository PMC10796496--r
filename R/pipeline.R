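# End-to-end pipeline: runs the full analysis chain on a patient-level
# cohort (or the built-in grouped fixture) and emits a consolidated report
# bundle mirroring the published table shapes, with every stage's
# parameters and the seed recorded.

#' Run the full risk-stratified HTE pipeline
#'
#' Stages, in order: baseline per-arm score distribution; endpoint 2x2
#' tests; the treatment + score logit per outcome with its postestimation
#' report; Sidak-corrected conditional margins; subgroup meta-analytic
#' heterogeneity (Mantel-Haenszel fixed + REML random effects, Egger when
#' enough strata); and the matching-smoothing HTE analysis per outcome.
#' Stage failures are caught and reported by stage name; partial output is
#' retained. The input is never mutated. A single global `seed` fans out
#' to per-stage seeds (`seed + stage offset`), so each stage is
#' individually reproducible.
#'
#' @param cohort Unit-record data frame with `arm`, a score column and the
#'   outcome columns, e.g. from [generate_cohort()] or
#'   [expand_cohort(cerehetis_cohort())][expand_cohort()].
#' @param outcomes Binary outcome columns to run (default those present
#'   among sht/any_ht/ffo).
#' @param score Score column name.
#' @param reps Bootstrap resamples for the HTE stage.
#' @param seed Global integer seed.
#' @param hte_ci `"bootstrap"` or `"analytic"` for the HTE stage.
#' @param out_dir Optional directory: each report is also written as JSON.
#' @return A named list (report bundle) of class `hte_report_bundle`.
#' @export
run_pipeline <- function(cohort, outcomes = NULL, score = "hti",
                         reps = 1000, seed = 1,
                         hte_ci = c("bootstrap", "analytic"),
                         out_dir = NULL) {
  hte_ci <- match.arg(hte_ci)
  if (is.null(outcomes))
    outcomes <- intersect(c("sht", "any_ht", "ffo"), names(cohort))
  stopifnot(length(outcomes) >= 0, score %in% names(cohort),
            "arm" %in% names(cohort))
  bundle <- list(provenance = list(
    package_version = as.character(utils::packageVersion("htematch")),
    seed = seed, reps = reps, score = score, outcomes = outcomes,
    n = nrow(cohort),
    config_hash = sum(utils::head(as.integer(charToRaw(paste(
      nrow(cohort), seed, reps, score, paste(outcomes, collapse = ",")))),
      1000))
  ))
  stage <- function(name, expr) {
    v <- tryCatch(expr, error = function(e) {
      warning("stage '", name, "' failed: ", conditionMessage(e))
      list(error = conditionMessage(e))
    })
    bundle[[name]] <<- v
  }

  grouped <- group_cohort(cohort, score, outcomes = outcomes)
  stage("baseline", {
    tab <- stats::aggregate(
      stats::setNames(list(cohort[[score]]), "n"),
      by = list(score = cohort[[score]], arm = cohort$arm), FUN = length)
    tab[order(tab$score, -tab$arm), ]
  })
  stage("endpoints", {
    do.call(rbind, lapply(outcomes, function(o) {
      e1 <- sum(cohort[[o]][cohort$arm == 1])
      n1 <- sum(cohort$arm == 1)
      e0 <- sum(cohort[[o]][cohort$arm == 0])
      n0 <- sum(cohort$arm == 0)
      ct <- contingency_test(e1, n1 - e1, e0, n0 - e0)
      data.frame(outcome = o, events_treated = e1, n_treated = n1,
                 events_control = e0, n_control = n0,
                 chi2 = ct$chi2, p = ct$p)
    }))
  })
  stage("models", {
    lapply(stats::setNames(outcomes, outcomes), function(o) {
      fit <- fit_logit(stats::as.formula(paste(o, "~ arm +", score)), cohort)
      list(coefficients = coef(fit), or = exp(coef(fit)),
           postestimation = unclass(postestimation(fit)))
    })
  })
  stage("margins", {
    lapply(stats::setNames(outcomes, outcomes), function(o) {
      fit <- fit_logit(stats::as.formula(paste(o, "~ arm +", score)), cohort)
      as.data.frame(conditional_margins(
        fit, sort(unique(cohort[[score]])), score = score))
    })
  })
  stage("meta", {
    lapply(stats::setNames(outcomes, outcomes), function(o) {
      st <- suppressMessages(make_studies(grouped, o))
      res <- list(mh_fixed = unclass(mh_fixed_rd(st))[
        c("pooled", "ci", "Q", "tau2", "i2", "h2")],
        reml_random = unclass(reml_random(st))[
          c("pooled", "ci", "Q", "tau2", "i2", "h2")])
      res$egger <- tryCatch(suppressWarnings(egger_test(st)),
                            error = function(e)
                              list(error = conditionMessage(e)))
      res
    })
  })
  stage("hte", {
    lapply(stats::setNames(outcomes, outcomes), function(i) {
      h <- hte_matchsmooth(cohort, outcome = i, score = score,
                           ci = hte_ci, reps = reps, seed = seed + 101L)
      list(score_effects = h$score_effects, bandwidths = h$bandwidths,
           propensity = coef(h$propensity$glm))
    })
  })
  class(bundle) <- "hte_report_bundle"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(bundle))
      jsonlite::write_json(bundle[[nm]],
                           file.path(out_dir, paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = NA, force = TRUE,
                           pretty = TRUE)
  }
  bundle
}

#' Render a report bundle as readable text
#'
#' @param bundle An `hte_report_bundle` from [run_pipeline()].
#' @return Character vector of report lines (also printable via `cat`).
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "hte_report_bundle"))
  pv <- bundle$provenance
  out <- c(
    "Risk-stratified HTE analysis report",
    sprintf("package htematch %s | n = %d | seed = %d | bootstrap reps = %d | config hash = %s",
            pv$package_version, pv$n, pv$seed, pv$reps, pv$config_hash),
    ""
  )
  if (length(pv$outcomes) == 0)
    return(c(out, "no outcomes requested"))
  if (!is.null(bundle$endpoints) && is.data.frame(bundle$endpoints)) {
    out <- c(out, "Endpoints (arm totals and Pearson chi-square):",
             utils::capture.output(print(bundle$endpoints, row.names = FALSE)),
             "")
  }
  for (o in pv$outcomes) {
    m <- bundle$models[[o]]
    if (!is.null(m$coefficients)) {
      pe <- m$postestimation
      out <- c(out, sprintf(
        "Model %s ~ arm + %s: AIC %.2f, BIC %.2f, McFadden %.3f, AUC %.2f",
        o, pv$score, pe$aic, pe$bic, pe$mcfadden, pe$auc))
    }
    mt <- bundle$meta[[o]]
    if (!is.null(mt$reml_random$i2))
      out <- c(out, sprintf(
        "  heterogeneity (REML): I2 = %.1f%%, H2 = %.2f, tau2 = %.3g",
        mt$reml_random$i2, mt$reml_random$h2, mt$reml_random$tau2))
    ht <- bundle$hte[[o]]
    if (!is.null(ht$score_effects)) {
      se <- ht$score_effects
      out <- c(out, "  matching-smoothing score effects:",
               sprintf("    score %s: TE %.3f [%.3f, %.3f], p %s",
                       se$score, se$te, se$ci_low, se$ci_high,
                       format.pval(se$p, digits = 2)))
    }
    out <- c(out, "")
  }
  out
}
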