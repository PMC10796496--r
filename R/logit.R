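# Binary-outcome logistic regression with the unit-level (Bernoulli)
# likelihood, plus conditional margins and a generic bootstrap engine.

#' Fit a binary logistic regression
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares (tolerance 1e-10 on the relative deviance change, at most 100
#' iterations). Frequency weights are expanded to unit records before
#' fitting, so grouped and unit-level data give identical coefficients and
#' the reported log-likelihood is always on the unit-level Bernoulli scale
#' (deviance = -2 log L). Perfect separation is detected and reported as an
#' error rather than silently penalized.
#'
#' @param formula Model formula with a 0/1 response.
#' @param data Data frame.
#' @param weights Optional nonnegative integer frequency weights (counts of
#'   identical records).
#' @return An object of class `blogit` with components `coefficients`,
#'   `vcov`, `loglik`, `loglik_null`, `deviance`, `n`, `k`, `fitted`,
#'   `model` (the expanded model frame) and the underlying `glm` fit.
#' @seealso [predict_prob()], [conditional_margins()], [postestimation()]
#' @export
fit_logit <- function(formula, data, weights = NULL) {
  stopifnot(is.data.frame(data))
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(data), all(weights >= 0),
              all(weights == round(weights)))
    data <- data[rep(seq_len(nrow(data)), weights), , drop = FALSE]
    rownames(data) <- NULL
  }
  ctrl <- stats::glm.control(epsilon = 1e-10, maxit = 100)
  fit <- stats::glm(formula, family = stats::binomial(), data = data,
                    control = ctrl)
  if (!fit$converged)
    stop("logistic fit did not converge within 100 iterations")
  if (any(abs(stats::coef(fit)) > 20, na.rm = TRUE) ||
      any(fit$fitted.values < 1e-10) || any(fit$fitted.values > 1 - 1e-10))
    stop("perfect (or quasi-complete) separation detected: ",
         "a coefficient diverged during fitting")
  if (anyNA(stats::coef(fit)))
    stop("design not full rank: aliased term(s) ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  y <- fit$y
  null <- stats::glm(y ~ 1, family = stats::binomial(), control = ctrl)
  structure(list(
    coefficients = stats::coef(fit),
    vcov = stats::vcov(fit),
    loglik = as.numeric(stats::logLik(fit)),
    loglik_null = as.numeric(stats::logLik(null)),
    deviance = -2 * as.numeric(stats::logLik(fit)),
    n = length(y),
    k = length(stats::coef(fit)),
    fitted = unname(fit$fitted.values),
    y = y,
    formula = formula,
    glm = fit
  ), class = "blogit")
}

#' @export
print.blogit <- function(x, ...) {
  cat("Binary logit:", deparse(x$formula), "\n")
  cat("n =", x$n, " logLik =", format(x$loglik, digits = 6),
      " deviance =", format(x$deviance, digits = 6), "\n\nCoefficients (OR):\n")
  print(cbind(estimate = x$coefficients, OR = exp(x$coefficients)), ...)
  invisible(x)
}

#' @export
summary.blogit <- function(object, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  q <- stats::qnorm(1 - (1 - level) / 2)
  tab <- cbind(
    estimate = object$coefficients, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    OR = exp(object$coefficients),
    or_low = exp(object$coefficients - q * se),
    or_high = exp(object$coefficients + q * se)
  )
  out <- list(coefficients = tab, loglik = object$loglik,
              loglik_null = object$loglik_null, n = object$n, k = object$k,
              formula = object$formula)
  class(out) <- "summary.blogit"
  out
}

#' @export
print.summary.blogit <- function(x, ...) {
  cat("Binary logit:", deparse(x$formula), "\n")
  cat("n =", x$n, " logLik =", format(x$loglik, digits = 6), "\n\n")
  stats::printCoefmat(x$coefficients[, 1:4, drop = FALSE], P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("\nOdds ratios (normal-based 95% CI):\n")
  print(round(x$coefficients[, 5:7, drop = FALSE], 4))
  invisible(x)
}

#' @export
coef.blogit <- function(object, ...) object$coefficients

#' @export
vcov.blogit <- function(object, ...) object$vcov

#' @export
logLik.blogit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
fitted.blogit <- function(object, ...) object$fitted

#' @export
residuals.blogit <- function(object, type = c("deviance", "pearson", "response"),
                             ...) {
  stats::residuals(object$glm, type = match.arg(type))
}

#' @export
predict.blogit <- function(object, newdata = NULL,
                           type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "response") return(object$fitted)
    return(unname(stats::predict(object$glm, type = "link")))
  }
  unname(stats::predict(object$glm, newdata = newdata, type = type))
}

#' Predicted event probability at a design point
#'
#' Inverse-logit of the linear predictor at the given covariate values.
#'
#' @param fit A `blogit` fit.
#' @param design_point One-row data frame (or list) of covariate values.
#' @return Probability in (0, 1).
#' @export
predict_prob <- function(fit, design_point) {
  stopifnot(inherits(fit, "blogit"))
  predict.blogit(fit, newdata = as.data.frame(design_point), type = "response")
}

#' Conditional marginal effects of treatment across score levels
#'
#' At each score level, computes the model-predicted event probability in
#' each arm (intervals formed on the logit scale and back-transformed, so
#' they respect (0, 1)) and the arm contrast (treated minus control) with a
#' delta-method standard error on the probability scale. With
#' `correction = "sidak"` the interval level is raised to
#' `1 - (1 - alpha)^(1/m)` across the `m` reported intervals, so corrected
#' intervals always contain the uncorrected ones. Levels outside the
#' observed score range are allowed but flagged.
#'
#' @param fit A `blogit` fit of an outcome on a treatment indicator plus a
#'   score.
#' @param levels Score values at which to evaluate.
#' @param treat,score Names of the treatment and score terms in the model.
#' @param correction `"sidak"` (default) or `"none"`.
#' @param alpha Familywise alpha (default 0.05).
#' @param family_size Number of intervals in the Sidak family. Default
#'   `NULL`: the intervals produced by this call (2 per level for the arm
#'   probabilities, 1 per level for the contrasts). When several outcome
#'   models are reported as one table, pass the total interval count.
#' @return An object of class `margin_set`: data frame with per-level arm
#'   probabilities with intervals, and the contrast with its interval and
#'   p-value.
#' @export
conditional_margins <- function(fit, levels, treat = "arm", score = NULL,
                                correction = c("sidak", "none"),
                                alpha = 0.05, family_size = NULL) {
  stopifnot(inherits(fit, "blogit"))
  correction <- match.arg(correction)
  if (is.null(score)) {
    nm <- setdiff(names(fit$coefficients), c("(Intercept)", treat))
    if (length(nm) != 1)
      stop("cannot infer the score term; pass `score` explicitly")
    score <- nm
  }
  obs <- fit$glm$model[[score]]
  if (any(levels < min(obs) | levels > max(obs)))
    message("note: some levels lie outside the observed score range ",
            "(extrapolation)")
  m_prob <- if (is.null(family_size)) 2 * length(levels) else family_size
  m_con <- if (is.null(family_size)) length(levels) else family_size
  a_prob <- if (correction == "sidak") 1 - (1 - alpha)^(1 / m_prob) else alpha
  a_con <- if (correction == "sidak") 1 - (1 - alpha)^(1 / m_con) else alpha
  zp <- stats::qnorm(1 - a_prob / 2)
  zc <- stats::qnorm(1 - a_con / 2)
  beta <- fit$coefficients
  V <- fit$vcov
  one_point <- function(arm_val, lev) {
    nd <- stats::setNames(data.frame(arm_val, lev), c(treat, score))
    x <- stats::model.matrix(stats::delete.response(stats::terms(fit$formula)),
                             nd)
    eta <- drop(x %*% beta)
    se_eta <- sqrt(drop(x %*% V %*% t(x)))
    p <- stats::plogis(eta)
    list(p = p, lo = stats::plogis(eta - zp * se_eta),
         hi = stats::plogis(eta + zp * se_eta),
         grad = drop(p * (1 - p) * x))   # d p / d beta
  }
  rows <- lapply(levels, function(lev) {
    t1 <- one_point(1, lev)
    t0 <- one_point(0, lev)
    g <- t1$grad - t0$grad
    se_d <- sqrt(drop(t(g) %*% V %*% g))
    d <- t1$p - t0$p
    data.frame(level = lev,
               p_treated = t1$p, p_treated_low = t1$lo, p_treated_high = t1$hi,
               p_control = t0$p, p_control_low = t0$lo, p_control_high = t0$hi,
               contrast = d, se = se_d,
               contrast_low = d - zc * se_d, contrast_high = d + zc * se_d,
               p_value = 2 * stats::pnorm(-abs(d / se_d)))
  })
  out <- do.call(rbind, rows)
  structure(out, correction = correction, alpha = alpha,
            class = c("margin_set", "data.frame"))
}

#' @export
print.margin_set <- function(x, digits = 3, ...) {
  cat("Conditional margins (interval correction:", attr(x, "correction"),
      ")\n")
  print(round(as.data.frame(x), digits))
  invisible(x)
}

#' Normal-based bootstrap confidence interval
#'
#' Nonparametric pairs bootstrap: resamples rows of `data` with replacement,
#' re-evaluates the statistic, and returns the point estimate plus/minus
#' `z * sd(bootstrap replicates)` (normal-based interval, the convention
#' used throughout the pipeline with 1,000 resamples). Resamples on which
#' the statistic is undefined (error or `NA`) are redrawn and counted.
#'
#' @param statistic Function `data -> numeric` (scalar or vector).
#' @param data Data frame of unit records.
#' @param reps Number of bootstrap resamples (>= 2; default 1000).
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param level Confidence level (default 0.95).
#' @return List with `estimate`, `se`, `low`, `high`, `reps`, `redrawn`.
#' @export
bootstrap_ci <- function(statistic, data, reps = 1000, seed = 1,
                         level = 0.95) {
  stopifnot(reps >= 2)
  est <- statistic(data)
  n <- nrow(data)
  set.seed(seed)
  redrawn <- 0L
  draws <- matrix(NA_real_, nrow = reps, ncol = length(est))
  b <- 1L
  while (b <= reps) {
    idx <- sample.int(n, n, replace = TRUE)
    v <- tryCatch(statistic(data[idx, , drop = FALSE]),
                  error = function(e) NULL, warning = function(w) NULL)
    if (is.null(v) || anyNA(v) || length(v) != length(est)) {
      redrawn <- redrawn + 1L
      if (redrawn > 50L * reps) stop("statistic undefined on most resamples")
      next
    }
    draws[b, ] <- v
    b <- b + 1L
  }
  se <- apply(draws, 2, stats::sd)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (redrawn > 0)
    message(redrawn, " resample(s) redrawn (statistic undefined)")
  list(estimate = est, se = se, low = est - z * se, high = est + z * se,
       reps = reps, redrawn = redrawn)
}
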