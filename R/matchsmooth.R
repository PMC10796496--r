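# Matching-smoothing estimation of heterogeneous treatment effects (HTE):
# unit-level kernel-matched treatment effects are smoothed against the
# propensity log-odds index with a local-linear (degree-1) Epanechnikov
# kernel fit; score-level effects are read off the curve at each risk
# score's matched index, with two-sided p-values from the z-score of the
# 95% interval.

#' Rule-of-thumb bandwidth
#'
#' Silverman-style plug-in width for the Epanechnikov kernel:
#' h = 2.34 * min(sd, IQR / 1.349) * n^(-1/5). Scale-equivariant; errors
#' when the values carry no spread (an explicit bandwidth is then needed).
#'
#' @param x Numeric values (>= 2 distinct).
#' @return Positive bandwidth; the kernel constant is attached as
#'   attribute `"constant"`.
#' @export
rule_of_thumb_bandwidth <- function(x) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2)
    stop("all values identical: supply an explicit bandwidth")
  spread <- min(stats::sd(x), stats::IQR(x) / 1.349)
  if (spread == 0) spread <- stats::sd(x)
  structure(2.34 * spread * length(x)^(-1 / 5), constant = 2.34)
}

#' Unit-level matched treatment effects
#'
#' For a treated unit i, d_i = y_i minus the kernel-matched control mean at
#' its index; for a control unit j, d_j = the kernel-matched treated mean
#' minus y_j. Every unit, treated or untreated, receives an effect.
#'
#' @param data Unit-record data frame.
#' @param propensity A `propensity` model for these units.
#' @param outcome Outcome column name.
#' @param treat Treatment column name.
#' @param bandwidth Matching bandwidth or `"auto"` (rule of thumb on the
#'   index).
#' @return List with `d` (per-unit effect), `index` (per-unit log-odds),
#'   `bandwidth`, `n_fallback`.
#' @export
unit_treatment_effects <- function(data, propensity, outcome, treat = "arm",
                                   bandwidth = "auto") {
  km <- kernel_match(data, propensity, outcome, treat,
                     scale = "index", bandwidth = bandwidth)
  y <- data[[outcome]]
  tr <- data[[treat]] == 1
  d <- ifelse(tr, y - km$counterfactual, km$counterfactual - y)
  list(d = d, index = propensity$index, bandwidth = km$bandwidth,
       n_fallback = km$n_fallback)
}

#' Local-linear smooth of unit treatment effects
#'
#' At each grid point x0, fits weighted least squares of the unit effects d
#' on (index - x0) with Epanechnikov weights K((index - x0)/h); the
#' intercept is the smoothed treatment effect. Degree-1 fitting reproduces
#' any d linear in the index exactly, and a constant d gives a constant
#' curve for any bandwidth. Pointwise normal-based intervals use the
#' homoscedastic weighted-regression variance, conditional on the unit
#' effects (the standard local-polynomial band; see the methods vignette
#' for its limitations relative to the bootstrap). Grid points with fewer
#' than 2 units of positive weight are dropped with a warning.
#'
#' @param unit_te Per-unit matched effects d.
#' @param unit_index Per-unit propensity index.
#' @param bandwidth Positive smoothing bandwidth h.
#' @param grid Evaluation points (default: 50 points over the index range).
#' @param level Confidence level for the bands.
#' @return Object of class `hte_curve`: data frame `grid`, `te`, `se`,
#'   `ci_low`, `ci_high` plus attributes (`bandwidth`, `kernel`, `degree`,
#'   `unit_te`, `unit_index`).
#' @export
smooth_te <- function(unit_te, unit_index, bandwidth,
                      grid = NULL, level = 0.95) {
  stopifnot(length(unit_te) == length(unit_index), bandwidth > 0)
  if (is.null(grid))
    grid <- seq(min(unit_index), max(unit_index), length.out = 50)
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- lapply(grid, function(x0) {
    u <- (unit_index - x0) / bandwidth
    w <- epanechnikov(u)
    if (sum(w > 0) < 2) return(NULL)
    X <- cbind(1, unit_index - x0)
    XtW <- t(X * w)
    A <- XtW %*% X
    if (!is.finite(rcond(A)) || rcond(A) < 1e-12) {
      # all weight on one index value: fall back to the weighted mean
      te <- sum(w * unit_te) / sum(w)
      r <- unit_te - te
      se <- sqrt(sum(w^2 * r^2) / sum(w)^2)
      return(data.frame(grid = x0, te = te, se = se))
    }
    Ainv <- solve(A)
    b <- Ainv %*% (XtW %*% unit_te)
    r <- unit_te - drop(X %*% b)
    # homoscedastic weighted-regression variance, conditional on the unit
    # effects (the standard local-polynomial pointwise band)
    sig2 <- sum(w * r^2) / sum(w)
    Vb <- sig2 * (Ainv %*% (t(X * w^2) %*% X) %*% Ainv)
    data.frame(grid = x0, te = b[1], se = sqrt(max(0, Vb[1, 1])))
  })
  drop_n <- sum(vapply(rows, is.null, logical(1)))
  if (drop_n > 0)
    warning(drop_n, " grid point(s) dropped (fewer than 2 effective units)")
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no grid point has enough effective units")
  out$ci_low <- out$te - z * out$se
  out$ci_high <- out$te + z * out$se
  rownames(out) <- NULL
  structure(out, bandwidth = bandwidth, kernel = "epanechnikov", degree = 1L,
            unit_te = unit_te, unit_index = unit_index, level = level,
            class = c("hte_curve", "data.frame"))
}

#' Interpolate a smoothed HTE curve
#'
#' Re-evaluates the local-linear fit of an [smooth_te()] curve at new index
#' values (an exact re-fit, not linear interpolation of the grid).
#'
#' @param object An `hte_curve`.
#' @param newindex Index values at which to evaluate.
#' @param ... Unused.
#' @return Data frame `grid`, `te`, `se`, `ci_low`, `ci_high`.
#' @export
predict.hte_curve <- function(object, newindex, ...) {
  out <- smooth_te(attr(object, "unit_te"), attr(object, "unit_index"),
                   attr(object, "bandwidth"), grid = newindex,
                   level = attr(object, "level"))
  as.data.frame(out)
}

#' Score-level treatment effects from a smoothed curve
#'
#' Evaluates the smoothed treatment effect at each risk score's matched
#' propensity index. The two-sided p-value is computed from the z-score of
#' the confidence interval: z = estimate / ((high - low) / (2 z_alpha)).
#'
#' @param curve An `hte_curve`.
#' @param score_to_index Named numeric: score value -> propensity index.
#' @param se_override Optional per-score standard errors (e.g. from a
#'   bootstrap) replacing the analytic ones.
#' @param level Confidence level.
#' @return Data frame with `score`, `propensity`, `te`, `ci_low`,
#'   `ci_high`, `p`.
#' @export
score_level_effects <- function(curve, score_to_index, se_override = NULL,
                                level = 0.95) {
  idx <- as.numeric(score_to_index)
  rng <- range(attr(curve, "unit_index"))
  tol <- 1e-8 + diff(rng) * 1e-6
  if (any(idx < rng[1] - tol | idx > rng[2] + tol))
    stop("score index outside the support of the propensity index")
  fit <- predict.hte_curve(curve, idx)
  se <- if (is.null(se_override)) fit$se else se_override
  z <- stats::qnorm(1 - (1 - level) / 2)
  te <- fit$te
  lo <- te - z * se
  hi <- te + z * se
  zs <- ifelse(se > 0, te / se, 0)
  data.frame(
    score = if (is.null(names(score_to_index)))
      seq_along(idx) - 1 else as.numeric(names(score_to_index)),
    propensity = idx, te = te, ci_low = lo, ci_high = hi,
    p = ifelse(se > 0, 2 * stats::pnorm(-abs(zs)), as.numeric(te == 0))
  )
}

#' Matching-smoothing heterogeneous treatment effect analysis
#'
#' The full pipeline: (1) propensity logit of treatment on the risk score;
#' (2) per-unit Epanechnikov kernel-matched treatment effects on the
#' log-odds index (rule-of-thumb bandwidth, floored at the index range);
#' (3) rule-of-thumb smoothing bandwidth, floored at twice the index range
#' so the local-linear fit stays near-global and well-conditioned when the
#' index is nearly degenerate; (4) local-linear smooth of the unit effects
#' against the index; (5) score-level effects at each observed score's
#' index with z-based p-values. Score-effect confidence intervals are
#' normal-based bootstrap intervals by default (the whole pipeline is
#' re-run on each resample, each resample's curve read off at its own
#' score-to-index map; 1,000 resamples), or the analytic
#' weighted-regression bands when `ci = "analytic"`; the plotted curve
#' always carries the analytic pointwise band.
#'
#' @param data Unit-record data frame with treatment, score and outcome
#'   columns.
#' @param outcome Outcome column name (binary 0/1 or integer-valued, e.g.
#'   mRS).
#' @param score Risk score column name.
#' @param treat Treatment column name.
#' @param match_bandwidth Matching bandwidth, or `"auto"` for the module
#'   bandwidth rule (rule of thumb floored at the index range, shared with
#'   the smoothing stage so matching and smoothing operate on the same
#'   scale).
#' @param smooth_bandwidth Smoothing bandwidth or `"auto"` (the same
#'   rule).
#' @param ci `"bootstrap"` (default) or `"analytic"`.
#' @param reps Bootstrap resamples.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return Object of class `hte_ms` with components `propensity`, `curve`
#'   (an `hte_curve`), `score_effects`, `unit` (per-unit d and index),
#'   `bandwidths`, `diagnostics`, `call`.
#' @examples
#' cohort <- expand_cohort(cerehetis_cohort())
#' fit <- hte_matchsmooth(cohort, outcome = "sht", ci = "analytic")
#' summary(fit)
#' @export
hte_matchsmooth <- function(data, outcome, score = "hti", treat = "arm",
                            match_bandwidth = "auto",
                            smooth_bandwidth = "auto",
                            ci = c("bootstrap", "analytic"),
                            reps = 1000, seed = 1, level = 0.95) {
  ci <- match.arg(ci)
  stopifnot(all(c(outcome, score, treat) %in% names(data)))
  scores <- sort(unique(data[[score]]))

  run_once <- function(d) {
    pm <- estimate_propensity(d, score, treat)
    rot <- rule_of_thumb_bandwidth(pm$index)
    rng <- diff(range(pm$index))
    # bandwidth floors for a near-degenerate index (randomized assignment):
    # matching at the index range so every unit's window reaches donors
    # across the support; smoothing at twice the range so every unit keeps
    # positive weight (|u| <= 1/2) at every evaluation point, stabilizing
    # the boundary variance of the near-global local-linear fit
    mb <- if (identical(match_bandwidth, "auto")) max(rot, rng)
    else match_bandwidth
    ut <- suppressMessages(
      unit_treatment_effects(d, pm, outcome, treat, mb))
    h_s <- if (identical(smooth_bandwidth, "auto")) max(rot, 2 * rng)
    else smooth_bandwidth
    sc_idx <- unname(stats::predict(
      pm$glm, newdata = stats::setNames(data.frame(scores), score),
      type = "link"))
    list(pm = pm, ut = ut, h_s = h_s, sc_idx = sc_idx)
  }

  full <- run_once(data)
  grid <- seq(min(full$ut$index), max(full$ut$index), length.out = 50)
  grid <- sort(unique(c(grid, full$sc_idx)))
  curve <- smooth_te(full$ut$d, full$ut$index, full$h_s, grid, level)
  sc_map <- stats::setNames(full$sc_idx, scores)

  boot_se <- NULL
  if (ci == "bootstrap") {
    # pipeline bootstrap: each resample refits the propensity model,
    # rematches, resmooths, and reads its curve off at its OWN score-to-
    # index map (the index scale is resample-specific because the
    # propensity slope is re-estimated)
    stat <- function(d) {
      r <- run_once(d)
      cv <- smooth_te(r$ut$d, r$ut$index, r$h_s,
                      grid = range(r$ut$index), level = level)
      predict.hte_curve(cv, r$sc_idx)$te
    }
    bs <- bootstrap_ci(stat, data, reps = reps, seed = seed, level = level)
    boot_se <- bs$se
  }
  sc_eff <- score_level_effects(curve, sc_map, se_override = boot_se,
                                level = level)

  structure(list(
    propensity = full$pm,
    curve = curve,
    score_effects = sc_eff,
    unit = data.frame(index = full$ut$index, d = full$ut$d,
                      arm = data[[treat]], score = data[[score]]),
    bandwidths = c(match = full$ut$bandwidth, smooth = full$h_s),
    diagnostics = list(n = nrow(data), n_fallback = full$ut$n_fallback,
                       ci = ci, reps = if (ci == "bootstrap") reps else 0,
                       seed = seed, outcome = outcome),
    call = match.call()
  ), class = "hte_ms")
}

#' @export
print.hte_ms <- function(x, digits = 3, ...) {
  cat("Matching-smoothing HTE analysis\n")
  cat("  outcome:", x$diagnostics$outcome, " n =", x$diagnostics$n, "\n")
  cat("  bandwidths: match =", signif(x$bandwidths["match"], 4),
      ", smooth =", signif(x$bandwidths["smooth"], 4),
      " (Epanechnikov, degree 1)\n")
  cat("  CI method:", x$diagnostics$ci,
      if (x$diagnostics$ci == "bootstrap")
        paste0("(", x$diagnostics$reps, " resamples, seed ",
               x$diagnostics$seed, ")"), "\n\n")
  print(round(x$score_effects, digits))
  invisible(x)
}

#' @export
summary.hte_ms <- function(object, ...) {
  se <- object$score_effects
  cat("Matching-smoothing HTE analysis of",
      object$diagnostics$outcome, "\n")
  cat("Propensity model:", deparse(object$propensity$formula), "\n")
  co <- summary(object$propensity$glm)$coefficients
  print(round(co, 4))
  cat("\nScore-level treatment effects:\n")
  print(cbind(round(se[, c("score", "propensity", "te", "ci_low",
                           "ci_high")], 3),
              p = format.pval(se$p, digits = 2)))
  cat("\nMean unit effect (matched ATE):",
      round(mean(object$unit$d), 4), "\n")
  invisible(object)
}

#' @export
coef.hte_ms <- function(object, ...) {
  stats::setNames(object$score_effects$te,
                  paste0("score", object$score_effects$score))
}

#' @export
predict.hte_ms <- function(object, newindex = NULL, ...) {
  if (is.null(newindex)) return(object$curve)
  predict.hte_curve(object$curve, newindex)
}

#' Plot a matching-smoothing HTE curve
#'
#' Smoothed treatment effect against the propensity index with pointwise
#' confidence band, unit effects as rug marks, and dashed verticals at each
#' score's matched index.
#'
#' @param x An `hte_ms` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hte_ms <- function(x, ...) {
  cv <- x$curve
  yl <- range(cv$ci_low, cv$ci_high)
  graphics::plot(cv$grid, cv$te, type = "n", ylim = yl,
                 xlab = "propensity index (log-odds)",
                 ylab = paste("treatment effect on", x$diagnostics$outcome),
                 ...)
  graphics::polygon(c(cv$grid, rev(cv$grid)),
                    c(cv$ci_low, rev(cv$ci_high)),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::lines(cv$grid, cv$te, lwd = 2, col = "steelblue4")
  graphics::abline(h = 0, lty = 3)
  graphics::abline(v = x$score_effects$propensity, lty = 2,
                   col = "grey50")
  graphics::axis(3, at = x$score_effects$propensity,
                 labels = x$score_effects$score, tick = FALSE, line = -1)
  graphics::rug(x$unit$index)
  invisible(x)
}
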