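# Postestimation battery for binary logits: specification, calibration,
# collinearity, fit, multiplicity and discrimination diagnostics used to
# choose among competing risk-score models.

#' Link test for specification error
#'
#' Refits the outcome on the fitted linear predictor and its square; a
#' significant squared term indicates a misspecified link or omitted
#' nonlinearity. Returns the Wald p-value of the squared term.
#'
#' @param fit A `blogit` fit with a non-constant linear predictor.
#' @return List with `p` (squared term), `coef` of the auxiliary fit.
#' @export
link_test <- function(fit) {
  stopifnot(inherits(fit, "blogit"))
  xb <- predict.blogit(fit, type = "link")
  if (stats::sd(xb) < 1e-12) stop("constant linear predictor")
  aux <- stats::glm(fit$y ~ xb + I(xb^2), family = stats::binomial())
  s <- summary(aux)$coefficients
  list(p = s["I(xb^2)", "Pr(>|z|)"], coef = stats::coef(aux))
}

#' Box-Tidwell test for nonlinearity in the logit
#'
#' For each continuous term x, augments the design with x * ln(x) and
#' reports the Wald p-value of the augmentation; a small p indicates the
#' term does not enter the logit linearly. Terms containing zeros (risk
#' scores start at 0) are shifted by `shift` inside the logarithm only
#' (x * ln(x + shift)); the shift applied is reported in the output.
#'
#' @param fit A `blogit` fit.
#' @param terms Character vector of continuous term names to test.
#' @param shift Additive shift used inside ln() for nonpositive values
#'   (default +1).
#' @return List with `p` (named per term) and `shift` (named per term,
#'   0 where no shift was needed).
#' @export
box_tidwell_test <- function(fit, terms, shift = 1) {
  stopifnot(inherits(fit, "blogit"))
  mf <- fit$glm$model
  p <- numeric(0)
  shifts <- numeric(0)
  for (tm in terms) {
    x <- mf[[tm]]
    if (is.null(x)) stop("term '", tm, "' not in the model frame")
    s <- if (min(x) <= 0) shift else 0
    if (min(x) + s <= 0)
      stop("term '", tm, "' has nonpositive values; configure a larger shift")
    aug <- x * log(x + s)
    d <- cbind(mf, .bt_aug = aug)
    f2 <- stats::update(stats::formula(fit$glm), . ~ . + .bt_aug)
    a <- stats::glm(f2, family = stats::binomial(), data = d,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
    p[tm] <- summary(a)$coefficients[".bt_aug", "Pr(>|z|)"]
    shifts[tm] <- s
  }
  list(p = p, shift = shifts)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Units are binned by sorted fitted probability with cutoffs at the order
#' statistics ceiling(j * n / g); ties share a bin, so with few distinct
#' covariate patterns the requested `groups` collapse to fewer bins. The
#' statistic sums (O - E)^2 / (E (1 - E/n)) over bins and is referred to a
#' chi-square with df = (actual bins) - 2.
#'
#' @param fit A `blogit` fit.
#' @param groups Requested number of bins (>= 3, default 10).
#' @return List with `chi2`, `df`, `p`, `groups` (actual bins) and the bin
#'   `table`.
#' @export
hosmer_lemeshow <- function(fit, groups = 10) {
  stopifnot(inherits(fit, "blogit"), groups >= 3)
  p <- fit$fitted
  y <- fit$y
  if (length(unique(p)) < 3) stop("fewer than 3 distinct fitted values")
  o <- order(p)
  ps <- p[o]
  ys <- y[o]
  n <- length(ps)
  cuts <- unique(ps[ceiling(seq_len(groups - 1) * n / groups)])
  bin <- findInterval(ps, cuts, left.open = TRUE) + 1L
  bin <- as.integer(factor(bin))
  obs <- tapply(ys, bin, sum)
  ex <- tapply(ps, bin, sum)
  ng <- tapply(ys, bin, length)
  contrib <- ifelse(ex == 0 | ex == ng, 0, (obs - ex)^2 / (ex * (1 - ex / ng)))
  chi2 <- sum(contrib)
  k <- length(obs)
  df <- k - 2L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE), groups = k,
       table = data.frame(n = as.integer(ng), observed = as.integer(obs),
                          expected = as.numeric(ex)))
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing each non-constant term on the
#' others. Aliased (perfectly collinear) terms are reported as `Inf`.
#'
#' @param design Data frame or numeric matrix of model terms (no response,
#'   no intercept column), at least two non-constant columns.
#' @return List with per-term `vif` and `mean`.
#' @export
variance_inflation <- function(design) {
  X <- as.matrix(as.data.frame(design))
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < 2) stop("need at least 2 non-constant terms")
  vif <- vapply(seq_len(ncol(X)), function(j) {
    r2 <- suppressWarnings(
      summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  list(vif = vif, mean = mean(vif))
}

#' Pseudo R-squared measures
#'
#' McFadden = 1 - ll/ll0; Cox-Snell = 1 - exp(2 (ll0 - ll)/n);
#' Nagelkerke = Cox-Snell / (1 - exp(2 ll0 / n)).
#'
#' @param fit A `blogit` fit.
#' @return List with `mcfadden`, `cox_snell`, `nagelkerke`.
#' @export
pseudo_r2 <- function(fit) {
  stopifnot(inherits(fit, "blogit"))
  ll <- fit$loglik
  ll0 <- fit$loglik_null
  n <- fit$n
  cs <- 1 - exp(2 * (ll0 - ll) / n)
  list(mcfadden = 1 - ll / ll0, cox_snell = cs,
       nagelkerke = cs / (1 - exp(2 * ll0 / n)))
}

#' Information criteria
#'
#' AIC = -2 ll + 2k; BIC = -2 ll + k ln(n), on the unit-level Bernoulli
#' log-likelihood.
#'
#' @param fit A `blogit` fit.
#' @return List with `aic`, `bic`, `k`, `n`.
#' @export
info_criteria <- function(fit) {
  stopifnot(inherits(fit, "blogit"))
  list(aic = -2 * fit$loglik + 2 * fit$k,
       bic = -2 * fit$loglik + fit$k * log(fit$n),
       k = fit$k, n = fit$n)
}

#' Likelihood-ratio test of nested logits
#'
#' chi2 = 2 (ll_full - ll_nested) on df = difference in parameter count.
#' The nested model's terms must be a subset of the full model's and both
#' must be fitted to the same units.
#'
#' @param nested,full `blogit` fits.
#' @return List with `chi2`, `df`, `p`.
#' @export
lr_test <- function(nested, full) {
  stopifnot(inherits(nested, "blogit"), inherits(full, "blogit"))
  if (nested$n != full$n)
    stop("models fitted to different numbers of units")
  if (!all(names(nested$coefficients) %in% names(full$coefficients)))
    stop("models are not nested: ",
         paste(setdiff(names(nested$coefficients),
                       names(full$coefficients)), collapse = ", "),
         " not in the full model")
  chi2 <- max(0, 2 * (full$loglik - nested$loglik))
  df <- full$k - nested$k
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Romano-Wolf stepdown adjustment from bootstrap statistics
#'
#' Core stepdown max-T adjustment: given observed statistics `t_obs`
#' (length m) and a B x m matrix of centered bootstrap statistics, computes
#' raw bootstrap p-values p_j = (1 + #{|t*_j| >= |t_j|}) / (B + 1) and
#' stepdown-adjusted p-values controlling the familywise error rate.
#' Adjusted p-values dominate the raw ones and are monotone along the
#' ordering of the observed statistics.
#'
#' @param t_obs Observed test statistics (length >= 1).
#' @param t_boot Matrix of bootstrap statistics (rows = resamples), already
#'   centered at the null.
#' @return List with `raw` and `adjusted` p-values (in input order).
#' @export
romano_wolf_adjust <- function(t_obs, t_boot) {
  t_boot <- as.matrix(t_boot)
  m <- length(t_obs)
  stopifnot(ncol(t_boot) == m)
  B <- nrow(t_boot)
  if (B < 100) warning("fewer than 100 resamples; adjustment is unstable")
  at <- abs(t_obs)
  ab <- abs(t_boot)
  raw <- vapply(seq_len(m), function(j) (1 + sum(ab[, j] >= at[j])) / (B + 1),
                numeric(1))
  ord <- order(at, decreasing = TRUE)
  adj <- numeric(m)
  prev <- 0
  remaining <- ord
  for (r in seq_len(m)) {
    j <- ord[r]
    maxdist <- apply(ab[, remaining, drop = FALSE], 1, max)
    pj <- (1 + sum(maxdist >= at[j])) / (B + 1)
    adj[j] <- max(prev, pj)
    prev <- adj[j]
    remaining <- setdiff(remaining, j)
  }
  list(raw = raw, adjusted = pmax(adj, raw))
}

#' Romano-Wolf adjusted p-values for a family of treatment models
#'
#' Convenience driver for the model family: pairs (nonparametric) bootstrap
#' of the cohort; each resample refits every model and collects the
#' treatment z-statistic, centered at its full-sample value; the centered
#' statistics feed [romano_wolf_adjust()].
#'
#' @param data Unit-record data frame.
#' @param formulas Named list of model formulas sharing the treatment term.
#' @param treat Name of the treatment coefficient (default `"arm"`).
#' @param reps Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return List with `raw`, `adjusted` (named per model) and `reps`.
#' @export
rw_treatment_pvalues <- function(data, formulas, treat = "arm", reps = 1000,
                                 seed = 1) {
  zstat <- function(d, f) {
    fit <- stats::glm(f, family = stats::binomial(), data = d)
    s <- summary(fit)$coefficients
    s[treat, "Estimate"] / s[treat, "Std. Error"]
  }
  t_obs <- vapply(formulas, function(f) zstat(data, f), numeric(1))
  set.seed(seed)
  n <- nrow(data)
  t_boot <- matrix(NA_real_, reps, length(formulas))
  b <- 1L
  while (b <= reps) {
    idx <- sample.int(n, n, replace = TRUE)
    v <- tryCatch(
      vapply(formulas, function(f) zstat(data[idx, , drop = FALSE], f),
             numeric(1)),
      error = function(e) NULL)
    if (is.null(v) || anyNA(v)) next
    t_boot[b, ] <- v - t_obs   # center at the full-sample statistic
    b <- b + 1L
  }
  rw <- romano_wolf_adjust(t_obs, t_boot)
  names(rw$raw) <- names(rw$adjusted) <- names(formulas)
  c(rw, list(reps = reps))
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC is the concordance probability of the fitted values (ties get half
#' credit); the CI is DeLong's asymptotic interval.
#'
#' @param fit A `blogit` fit with both outcome classes present.
#' @param level Confidence level.
#' @return List with `auc`, `ci` (length 2).
#' @export
roc_auc <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "blogit"))
  if (length(unique(fit$y)) < 2) stop("one-class outcome")
  r <- pROC::roc(fit$y, fit$fitted, quiet = TRUE, direction = "<")
  ci <- pROC::ci.auc(r, conf.level = level, method = "delong")
  list(auc = as.numeric(pROC::auc(r)), ci = as.numeric(ci)[c(1, 3)])
}

#' Compare two correlated AUCs
#'
#' DeLong test for paired ROC curves (same units, same outcome); reported
#' as a 1-df chi-square contrast.
#'
#' @param fit_a,fit_b `blogit` fits on the same units and outcome.
#' @return List with `chi2`, `df` (= 1), `p`, and the two AUCs.
#' @export
compare_auc <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "blogit"), inherits(fit_b, "blogit"))
  if (fit_a$n != fit_b$n || !all(fit_a$y == fit_b$y))
    stop("fits must share the same units and outcome")
  ra <- pROC::roc(fit_a$y, fit_a$fitted, quiet = TRUE, direction = "<")
  rb <- pROC::roc(fit_b$y, fit_b$fitted, quiet = TRUE, direction = "<")
  if (isTRUE(all.equal(fit_a$fitted, fit_b$fitted)))
    return(list(chi2 = 0, df = 1L, p = 1,
                auc = c(as.numeric(pROC::auc(ra)), as.numeric(pROC::auc(rb)))))
  tt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  z <- as.numeric(tt$statistic)
  list(chi2 = z^2, df = 1L, p = stats::pchisq(z^2, 1, lower.tail = FALSE),
       auc = c(as.numeric(pROC::auc(ra)), as.numeric(pROC::auc(rb))))
}

#' Full postestimation report for a binary logit
#'
#' Bundles the whole battery: link test, Box-Tidwell, Hosmer-Lemeshow,
#' mean VIF (when the design has >= 2 terms), deviance, likelihood ratio
#' against the null, pseudo R-squared, information criteria and AUC.
#'
#' @param fit A `blogit` fit.
#' @param bt_terms Continuous terms for the Box-Tidwell test (default: all
#'   non-treatment terms).
#' @param treat Treatment term name (excluded from Box-Tidwell).
#' @param hl_groups Requested Hosmer-Lemeshow bins.
#' @return Object of class `postestimation_report` (a list).
#' @export
postestimation <- function(fit, bt_terms = NULL, treat = "arm",
                           hl_groups = 10) {
  stopifnot(inherits(fit, "blogit"))
  mf <- fit$glm$model
  terms_all <- setdiff(names(mf), names(mf)[1])
  if (is.null(bt_terms)) bt_terms <- setdiff(terms_all, treat)
  lt <- link_test(fit)
  bt <- if (length(bt_terms)) box_tidwell_test(fit, bt_terms) else NULL
  hl <- hosmer_lemeshow(fit, hl_groups)
  vifs <- if (length(terms_all) >= 2)
    variance_inflation(mf[terms_all]) else NULL
  pr2 <- pseudo_r2(fit)
  ic <- info_criteria(fit)
  lr_chi2 <- max(0, 2 * (fit$loglik - fit$loglik_null))
  lr_df <- fit$k - 1L
  auc <- roc_auc(fit)
  structure(list(
    link_test_p = lt$p,
    box_tidwell_p = bt$p, box_tidwell_shift = bt$shift,
    hl_chi2 = hl$chi2, hl_df = hl$df, hl_p = hl$p,
    mean_vif = if (is.null(vifs)) NA_real_ else vifs$mean,
    deviance = fit$deviance,
    lr_chi2 = lr_chi2, lr_df = lr_df,
    lr_p = stats::pchisq(lr_chi2, lr_df, lower.tail = FALSE),
    mcfadden = pr2$mcfadden, cox_snell = pr2$cox_snell,
    nagelkerke = pr2$nagelkerke,
    aic = ic$aic, bic = ic$bic,
    auc = auc$auc, auc_ci = auc$ci,
    n = fit$n, k = fit$k
  ), class = "postestimation_report")
}

#' @export
print.postestimation_report <- function(x, digits = 3, ...) {
  cat("Postestimation report (n =", x$n, ", k =", x$k, ")\n")
  cat("  link test p:        ", round(x$link_test_p, digits), "\n")
  if (!is.null(x$box_tidwell_p))
    cat("  Box-Tidwell p:      ",
        paste(names(x$box_tidwell_p), round(x$box_tidwell_p, digits),
              collapse = "; "), "\n")
  cat("  Hosmer-Lemeshow:    ", round(x$hl_chi2, 2), "(df", x$hl_df, "), p =",
      round(x$hl_p, digits), "\n")
  cat("  mean VIF:           ", round(x$mean_vif, 2), "\n")
  cat("  deviance:           ", round(x$deviance, 2), "\n")
  cat("  LR chi2 (df):       ", round(x$lr_chi2, 2), "(", x$lr_df, "), p =",
      format.pval(x$lr_p, digits = 2), "\n")
  cat("  pseudo R2 (McF/CS/N):", round(x$mcfadden, digits),
      round(x$cox_snell, digits), round(x$nagelkerke, digits), "\n")
  cat("  AIC / BIC:          ", round(x$aic, 2), "/", round(x$bic, 2), "\n")
  cat("  AUC (CI):           ", round(x$auc, 2), "(",
      round(x$auc_ci[1], 2), "-", round(x$auc_ci[2], 2), ")\n")
  invisible(x)
}

#' Rank candidate models by their postestimation reports
#'
#' Deterministic ranking by (lower AIC, then lower BIC, then higher AUC).
#' Exact ties on all three criteria are declared, never silently broken.
#'
#' @param reports Named list of `postestimation_report`s (>= 2).
#' @return List with `ranking` (model names, best first), `tied` (logical),
#'   and a `criteria` data frame.
#' @export
select_model <- function(reports) {
  stopifnot(length(reports) >= 2)
  if (is.null(names(reports)))
    names(reports) <- paste0("model", seq_along(reports))
  crit <- data.frame(
    model = names(reports),
    aic = vapply(reports, function(r) r$aic, numeric(1)),
    bic = vapply(reports, function(r) r$bic, numeric(1)),
    auc = vapply(reports, function(r) r$auc, numeric(1))
  )
  ord <- order(crit$aic, crit$bic, -crit$auc)
  crit <- crit[ord, , drop = FALSE]
  rownames(crit) <- NULL
  tied <- nrow(crit) >= 2 &&
    isTRUE(all.equal(unlist(crit[1, -1]), unlist(crit[2, -1])))
  list(ranking = crit$model, tied = tied, criteria = crit)
}
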