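# Subgroup-as-"study" meta-analytic heterogeneity of treatment effects:
# each risk-score stratum is treated as an independent two-arm study.
# Binary endpoints use the risk difference (Mantel-Haenszel fixed effects);
# continuous endpoints use Hedges' g (inverse-variance fixed effects); both
# support REML random effects with the Higgins-Thompson I^2/H^2, plus the
# Egger small-study test and forest-plot data. Model fitting is delegated
# to metafor.

#' Build study rows from a grouped cohort (binary outcome)
#'
#' One "study" per score stratum with treated/control sizes and events, the
#' risk difference, and its within-study variance
#' p1(1-p1)/n1 + p0(1-p0)/n0 (no continuity correction; zero-event cells
#' are allowed, the variance then coming from the other arm). Strata with
#' an empty arm carry no contrast and are dropped when
#' `drop_empty_arm = TRUE` (with a message).
#'
#' @param grouped A `grouped_cohort` (see [group_cohort()]).
#' @param outcome Outcome column of the grouped cohort.
#' @param drop_empty_arm Drop strata where either arm has no subjects.
#' @return Data frame of class `study_rows`: `label`, `n1`, `e1`, `n0`,
#'   `e0`, `effect`, `variance`.
#' @export
make_studies <- function(grouped, outcome, drop_empty_arm = TRUE) {
  stopifnot(inherits(grouped, "grouped_cohort"),
            outcome %in% attr(grouped, "outcomes"))
  sc <- sort(unique(grouped$score))
  rows <- lapply(sc, function(s) {
    t1 <- grouped[grouped$score == s & grouped$arm == 1, ]
    t0 <- grouped[grouped$score == s & grouped$arm == 0, ]
    n1 <- if (nrow(t1)) t1$n else 0L
    n0 <- if (nrow(t0)) t0$n else 0L
    e1 <- if (nrow(t1)) t1[[outcome]] else 0L
    e0 <- if (nrow(t0)) t0[[outcome]] else 0L
    data.frame(label = s, n1 = n1, e1 = e1, n0 = n0, e0 = e0)
  })
  d <- do.call(rbind, rows)
  if (drop_empty_arm && any(d$n1 == 0 | d$n0 == 0)) {
    dropped <- d$label[d$n1 == 0 | d$n0 == 0]
    message("stratum(s) dropped for an empty arm: ",
            paste(dropped, collapse = ", "))
    d <- d[d$n1 > 0 & d$n0 > 0, , drop = FALSE]
  }
  p1 <- d$e1 / d$n1
  p0 <- d$e0 / d$n0
  d$effect <- p1 - p0
  d$variance <- p1 * (1 - p1) / d$n1 + p0 * (1 - p0) / d$n0
  rownames(d) <- NULL
  structure(d, measure = "RD", class = c("study_rows", "data.frame"))
}

#' Build study rows from unit records (continuous outcome, Hedges' g)
#'
#' One "study" per score stratum with per-arm means and SDs; the effect is
#' Hedges' g (small-sample corrected standardized mean difference)
#' g = J (m1 - m0) / s_pooled, J = 1 - 3/(4 df - 1), df = n1 + n0 - 2, with
#' its usual large-sample variance.
#'
#' @param data Unit-record data frame.
#' @param outcome Continuous outcome column (e.g. `mrs90`).
#' @param score,treat Column names.
#' @param drop_empty_arm Drop strata with an empty arm.
#' @return Data frame of class `study_rows` (measure `"SMD"`).
#' @export
make_studies_smd <- function(data, outcome, score = "hti", treat = "arm",
                             drop_empty_arm = TRUE) {
  sc <- sort(unique(data[[score]]))
  rows <- lapply(sc, function(s) {
    y1 <- data[[outcome]][data[[score]] == s & data[[treat]] == 1]
    y0 <- data[[outcome]][data[[score]] == s & data[[treat]] == 0]
    data.frame(label = s, n1 = length(y1), m1 = mean(y1), sd1 = stats::sd(y1),
               n0 = length(y0), m0 = mean(y0), sd0 = stats::sd(y0))
  })
  d <- do.call(rbind, rows)
  if (drop_empty_arm && any(d$n1 < 2 | d$n0 < 2)) {
    message("stratum(s) dropped for an empty or singleton arm: ",
            paste(d$label[d$n1 < 2 | d$n0 < 2], collapse = ", "))
    d <- d[d$n1 >= 2 & d$n0 >= 2, , drop = FALSE]
  }
  df <- d$n1 + d$n0 - 2
  sp <- sqrt(((d$n1 - 1) * d$sd1^2 + (d$n0 - 1) * d$sd0^2) / df)
  J <- 1 - 3 / (4 * df - 1)
  d$effect <- J * (d$m1 - d$m0) / sp
  d$variance <- (d$n1 + d$n0) / (d$n1 * d$n0) +
    d$effect^2 / (2 * (d$n1 + d$n0))
  if (any(!is.finite(d$variance))) stop("zero pooled SD in a stratum")
  rownames(d) <- NULL
  structure(d, measure = "SMD", class = c("study_rows", "data.frame"))
}

.meta_result <- function(pooled, ci, Q, Qdf, tau2, i2, h2, model, studies,
                         se = NA_real_) {
  structure(list(pooled = pooled, se = se, ci = ci, Q = Q, Q_df = Qdf,
                 Q_p = stats::pchisq(Q, Qdf, lower.tail = FALSE),
                 tau2 = tau2, i2 = i2, h2 = h2, model = model,
                 k = nrow(studies), studies = studies),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, digits = 4, ...) {
  cat("Meta-analysis (", x$model, "), k = ", x$k, " studies\n", sep = "")
  cat("  pooled effect:", round(x$pooled, digits),
      " 95% CI [", round(x$ci[1], digits), ",", round(x$ci[2], digits),
      "]\n")
  cat("  Q =", round(x$Q, 3), "(df", x$Q_df, "), p =",
      format.pval(x$Q_p, digits = 2), "\n")
  cat("  tau2 =", signif(x$tau2, 4), " I2 =", round(x$i2, 1),
      "%  H2 =", round(x$h2, 2), "\n")
  invisible(x)
}

#' Fixed-effects Mantel-Haenszel pooled risk difference
#'
#' MH weights n1 n0 / (n1 + n0); the pooled interval uses the
#' Greenland-Robins variance. Heterogeneity (Q-based I^2 and H^2) is
#' reported from Cochran's Q.
#'
#' @param studies Binary `study_rows` from [make_studies()].
#' @return A `meta_result`.
#' @export
mh_fixed_rd <- function(studies) {
  stopifnot(inherits(studies, "study_rows"),
            attr(studies, "measure") == "RD")
  if (all(studies$variance == 0)) stop("all strata degenerate")
  fit <- metafor::rma.mh(ai = studies$e1, n1i = studies$n1,
                         ci = studies$e0, n2i = studies$n0,
                         measure = "RD", add = 0, to = "none")
  Q <- fit$QE
  df <- fit$k - 1
  .meta_result(as.numeric(fit$beta), c(fit$ci.lb, fit$ci.ub), Q, df,
               tau2 = 0,
               i2 = max(0, 100 * (Q - df) / Q),
               h2 = max(1, Q / df),
               model = "mh_fixed", studies = studies, se = fit$se)
}

#' Fixed-effects inverse-variance pooled standardized mean difference
#'
#' Inverse-variance pooling of Hedges' g study effects.
#'
#' @param studies Continuous `study_rows` from [make_studies_smd()].
#' @return A `meta_result`.
#' @export
iv_fixed_smd <- function(studies) {
  stopifnot(inherits(studies, "study_rows"),
            attr(studies, "measure") == "SMD")
  fit <- metafor::rma(yi = studies$effect, vi = studies$variance,
                      method = "FE")
  Q <- fit$QE
  df <- fit$k - 1
  .meta_result(as.numeric(fit$beta), c(fit$ci.lb, fit$ci.ub), Q, df,
               tau2 = 0, i2 = max(0, 100 * (Q - df) / Q),
               h2 = max(1, Q / df),
               model = "iv_fixed", studies = studies, se = fit$se)
}

#' Random-effects REML meta-analysis
#'
#' Restricted maximum-likelihood estimate of the between-study variance
#' tau^2 with inverse-variance weights 1/(v_i + tau^2). I^2 and H^2 use the
#' Higgins-Thompson typical within-study variance
#' s^2 = (k-1) \eqn{\sum w / ((\sum w)^2 - \sum w^2)}, w = 1/v:
#' I^2 = 100 tau^2/(tau^2 + s^2), H^2 = (tau^2 + s^2)/s^2.
#'
#' @param studies A `study_rows` table (either measure).
#' @return A `meta_result`.
#' @export
reml_random <- function(studies) {
  stopifnot(inherits(studies, "study_rows"), nrow(studies) >= 2)
  fit <- metafor::rma(yi = studies$effect, vi = studies$variance,
                      method = "REML", control = list(maxiter = 1000))
  .meta_result(as.numeric(fit$beta), c(fit$ci.lb, fit$ci.ub),
               fit$QE, fit$k - 1, tau2 = fit$tau2,
               i2 = as.numeric(fit$I2), h2 = as.numeric(fit$H2),
               model = "reml_random", studies = studies, se = fit$se)
}

#' Egger test for small-study effects
#'
#' Weighted regression of the effect on its standard error with weights
#' 1/v (equivalently, of the standardized effect on precision); the test is
#' the two-sided p of the asymmetry coefficient. Fewer than ten studies
#' makes the test weak (warning); fewer than three is an error, as is a set
#' of identical variances (degenerate regression).
#'
#' @param studies A `study_rows` table.
#' @return List with `intercept` (asymmetry estimate), `se`, `p`.
#' @export
egger_test <- function(studies) {
  stopifnot(inherits(studies, "study_rows"))
  k <- nrow(studies)
  if (k < 3) stop("Egger test needs at least 3 studies")
  if (k < 10) warning("fewer than 10 studies; the Egger test has low power")
  if (stats::sd(studies$variance) < 1e-14)
    stop("identical within-study variances: regression is degenerate")
  fit <- metafor::rma(yi = studies$effect, vi = studies$variance,
                      method = "FE")
  rt <- metafor::regtest(fit, model = "lm", predictor = "sei")
  list(intercept = as.numeric(rt$est), se = as.numeric(rt$se),
       p = as.numeric(rt$pval))
}

#' Forest-plot data
#'
#' Per-study effects, intervals and percentage weights (proportional to
#' 1/(v_i + tau^2), summing to 100) plus the pooled row.
#'
#' @param result A `meta_result`.
#' @return Data frame with one row per study and a final pooled row.
#' @export
forest_data <- function(result) {
  stopifnot(inherits(result, "meta_result"))
  st <- result$studies
  w <- 1 / (st$variance + result$tau2)
  w <- 100 * w / sum(w)
  z <- stats::qnorm(0.975)
  se <- sqrt(st$variance)
  out <- data.frame(
    label = as.character(st$label),
    effect = st$effect,
    low = st$effect - z * se,
    high = st$effect + z * se,
    weight = w
  )
  rbind(out, data.frame(label = "pooled", effect = result$pooled,
                        low = result$ci[1], high = result$ci[2],
                        weight = 100))
}
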