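# Generalized ordered logistic regression for ordinal outcomes (day-90 mRS)
# under proportional and partial-proportional odds, with the Brant test of
# the parallel-lines assumption and ordinal conditional margins.
#
# Parameterization (the gologit convention): for cutpoints j = 1..J-1,
#   P(Y > c_j | x) = plogis(alpha_j + x' beta_j),
# with beta_j = beta shared across cutpoints under proportional odds and
# freed for the relaxed terms under partial proportional odds.

#' Fit a generalized ordered logit
#'
#' Maximum likelihood over cumulative logits. `mode = "proportional"`
#' constrains every slope to be equal across cutpoints (the parallel-lines
#' model); `mode = "partial"` frees the slopes of the terms named in
#' `relax`. With `relax` empty the partial fit reduces exactly to the
#' proportional one, and with a two-category outcome the model is an
#' ordinary binary logit. Outcome categories observed zero times are merged
#' into the adjacent lower category (with a message). Relaxed-slope models
#' can imply negative category probabilities at some design points; when
#' this happens during fitting the probabilities are floored at a small
#' positive value and the fit is flagged (`negative_prob_warning`).
#'
#' @param formula Model formula; the response is an integer ordinal score
#'   (e.g. mRS 0-6).
#' @param data Data frame.
#' @param mode `"proportional"` or `"partial"`.
#' @param relax Character vector of terms whose slopes vary by cutpoint
#'   (partial mode). Default `NULL`: in partial mode, all terms.
#' @return Object of class `gologit`: `thresholds` (per-cutpoint
#'   intercepts), `coefficients` (matrix, cutpoints x terms), `vcov`,
#'   `loglik`, `categories`, `constraint_map`, `converged`.
#' @export
fit_ordered <- function(formula, data,
                        mode = c("proportional", "partial"), relax = NULL) {
  mode <- match.arg(mode)
  mf <- stats::model.frame(formula, data)
  y_raw <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  terms_nm <- colnames(X)

  lev <- sort(unique(y_raw))
  counts <- table(factor(y_raw, levels = lev))
  # categories come from the observed values, so none is empty by
  # construction; unobserved intermediate scores simply do not open a cutpoint
  y <- match(y_raw, lev)                 # 1..J
  J <- length(lev)
  if (J < 2) stop("outcome has a single category")

  if (mode == "partial") {
    if (is.null(relax)) relax <- terms_nm
    if (!all(relax %in% terms_nm))
      stop("relax names unknown term(s): ",
           paste(setdiff(relax, terms_nm), collapse = ", "))
  } else relax <- character(0)
  shared <- setdiff(terms_nm, relax)

  nc <- J - 1                       # cutpoints
  m <- length(terms_nm)
  n_par <- nc + length(shared) + nc * length(relax)

  # parameter layout: [alpha_1..alpha_nc | beta_shared | beta_relax(by term, by cutpoint)]
  unpack <- function(theta) {
    alpha <- theta[seq_len(nc)]
    B <- matrix(0, nc, m, dimnames = list(NULL, terms_nm))
    pos <- nc
    for (tm in shared) {
      pos <- pos + 1
      B[, tm] <- theta[pos]
    }
    for (tm in relax) {
      B[, tm] <- theta[pos + seq_len(nc)]
      pos <- pos + nc
    }
    list(alpha = alpha, B = B)
  }

  eps <- 1e-10
  nll <- function(theta) {
    pa <- unpack(theta)
    G <- stats::plogis(matrix(pa$alpha, nrow(X), nc, byrow = TRUE) +
                         X %*% t(pa$B))    # n x nc, P(Y > c_j)
    Gfull <- cbind(1, G, 0)
    pr <- Gfull[cbind(seq_len(nrow(X)), y)] -
      Gfull[cbind(seq_len(nrow(X)), y + 1)]
    -sum(log(pmax(pr, eps)))
  }
  grad <- function(theta) {
    pa <- unpack(theta)
    Eta <- matrix(pa$alpha, nrow(X), nc, byrow = TRUE) + X %*% t(pa$B)
    G <- stats::plogis(Eta)
    gp <- G * (1 - G)                 # d plogis
    Gfull <- cbind(1, G, 0)
    pr <- Gfull[cbind(seq_len(nrow(X)), y)] -
      Gfull[cbind(seq_len(nrow(X)), y + 1)]
    pr <- pmax(pr, eps)
    # d ll_i / d eta_j: +gp_j/pr for j = y-1, -gp_j/pr for j = y
    D <- matrix(0, nrow(X), nc)
    jlow <- y - 1
    sel <- jlow >= 1
    D[cbind(which(sel), jlow[sel])] <- gp[cbind(which(sel), jlow[sel])] /
      pr[sel]
    sel2 <- y <= nc
    D[cbind(which(sel2), y[sel2])] <- D[cbind(which(sel2), y[sel2])] -
      gp[cbind(which(sel2), y[sel2])] / pr[sel2]
    g_alpha <- colSums(D)
    g <- numeric(length(theta))
    g[seq_len(nc)] <- g_alpha
    pos <- nc
    for (tm in shared) {
      pos <- pos + 1
      g[pos] <- sum(rowSums(D) * X[, tm])
    }
    for (tm in relax) {
      g[pos + seq_len(nc)] <- colSums(D * X[, tm])
      pos <- pos + nc
    }
    -g
  }

  # starting values: marginal cumulative logits, zero slopes
  cum <- cumsum(counts) / length(y)
  a0 <- stats::qlogis(pmin(pmax(1 - cum[seq_len(nc)], 1e-4), 1 - 1e-4))
  theta0 <- c(a0, rep(0, n_par - nc))
  opt <- stats::optim(theta0, nll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12),
                      hessian = TRUE)
  if (opt$convergence != 0)
    stop("ordered logit did not converge (optim code ", opt$convergence, ")")
  pa <- unpack(opt$par)
  V <- tryCatch(solve(opt$hessian), error = function(e) {
    warning("Hessian singular; covariance via pseudo-inverse")
    ev <- eigen(opt$hessian, symmetric = TRUE)
    keep <- ev$values > 1e-10 * max(ev$values)
    ev$vectors[, keep] %*% diag(1 / ev$values[keep], sum(keep)) %*%
      t(ev$vectors[, keep])
  })

  # flag negative implied probabilities at the MLE
  G <- stats::plogis(matrix(pa$alpha, nrow(X), nc, byrow = TRUE) +
                       X %*% t(pa$B))
  Gfull <- cbind(1, G, 0)
  anyneg <- any(Gfull[, seq_len(J)] - Gfull[, seq_len(J) + 1] < -1e-8)
  if (anyneg)
    warning("some fitted category probabilities are negative; ",
            "they are clipped for reporting but indicate a strained ",
            "partial-odds specification")

  par_names <- c(paste0("cut", seq_len(nc)),
                 shared,
                 unlist(lapply(relax, function(tm)
                   paste0(tm, ":cut", seq_len(nc)))))
  names(opt$par) <- par_names
  dimnames(V) <- list(par_names, par_names)
  structure(list(
    thresholds = stats::setNames(pa$alpha, paste0("cut", seq_len(nc))),
    coefficients = pa$B,
    par = opt$par,
    vcov = V,
    loglik = -opt$value,
    n = nrow(X),
    categories = lev,
    category_counts = as.integer(counts),
    mode = mode,
    constraint_map = list(shared = shared, relaxed = relax),
    negative_prob_warning = anyneg,
    formula = formula,
    X = X, y = y,
    converged = TRUE
  ), class = "gologit")
}

#' @export
print.gologit <- function(x, ...) {
  cat("Generalized ordered logit (", x$mode, " odds), n = ", x$n,
      ", categories: ", paste(x$categories, collapse = " "), "\n", sep = "")
  cat("logLik =", format(x$loglik, digits = 6), "\n\nThresholds:\n")
  print(round(x$thresholds, 4))
  cat("\nSlopes (rows = cutpoints):\n")
  print(round(x$coefficients, 4))
  if (length(x$constraint_map$relaxed))
    cat("relaxed terms:", paste(x$constraint_map$relaxed, collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
coef.gologit <- function(object, ...) object$coefficients

#' @export
logLik.gologit <- function(object, ...) {
  structure(object$loglik, df = length(object$par), nobs = object$n,
            class = "logLik")
}

#' @export
vcov.gologit <- function(object, ...) object$vcov

#' Predicted category probabilities from a generalized ordered logit
#'
#' @param object A `gologit` fit.
#' @param newdata Data frame of covariate values (default: fitting data).
#' @param ... Unused.
#' @return Matrix of category probabilities (columns = outcome categories).
#'   Probabilities implied negative by a partial-odds fit are clipped to 0
#'   and renormalized.
#' @export
predict.gologit <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$X else {
    mm <- stats::model.matrix(
      stats::delete.response(stats::terms(object$formula)), newdata)
    mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
  }
  nc <- length(object$thresholds)
  G <- stats::plogis(matrix(object$thresholds, nrow(X), nc, byrow = TRUE) +
                       X %*% t(object$coefficients))
  Gfull <- cbind(1, G, 0)
  P <- Gfull[, seq_len(nc + 1), drop = FALSE] -
    Gfull[, seq_len(nc + 1) + 1, drop = FALSE]
  P <- pmax(P, 0)
  P <- P / rowSums(P)
  colnames(P) <- as.character(object$categories)
  P
}

#' Brant test of the parallel-lines assumption
#'
#' Fits a separate binary logit over each cutpoint (indicator Y > c_j) and
#' Wald-tests equality of each slope across cutpoints, using the
#' cross-cutpoint covariance implied by the shared design. The global
#' statistic has df = (number of tested terms) x (J - 2); per-term
#' statistics have df = J - 2.
#'
#' @param fit A proportional-odds `gologit` fit with >= 3 categories.
#' @return List with `chi2`, `df`, `p` and a per-term `breakdown` data
#'   frame.
#' @export
brant_test <- function(fit) {
  stopifnot(inherits(fit, "gologit"))
  if (fit$mode != "proportional")
    stop("the Brant test applies to the proportional-odds fit")
  J <- length(fit$categories)
  if (J < 3) stop("need at least 3 outcome categories")
  X <- fit$X
  y <- fit$y
  n <- nrow(X)
  m <- ncol(X)
  nc <- J - 1
  X1 <- cbind(1, X)
  betas <- matrix(NA_real_, nc, m)       # slope estimates per cutpoint
  Pj <- matrix(NA_real_, n, nc)          # fitted P(Y > c_j)
  XtWXinv <- vector("list", nc)
  for (j in seq_len(nc)) {
    z <- as.integer(y > j)
    if (all(z == 0) || all(z == 1))
      stop("cutpoint ", j, " splits off an empty side")
    g <- stats::glm.fit(X1, z, family = stats::binomial())
    betas[j, ] <- g$coefficients[-1]
    Pj[, j] <- g$fitted.values
    W <- Pj[, j] * (1 - Pj[, j])
    XtWXinv[[j]] <- solve(crossprod(X1, X1 * W))
  }
  # joint covariance of the stacked slope vectors (Brant 1990)
  V <- matrix(0, nc * m, nc * m)
  for (j in seq_len(nc)) for (l in j:nc) {
    if (j == l) {
      Vjl <- XtWXinv[[j]]
    } else {
      # for j < l: cov uses W_jl = P_l - P_j P_l  (z_j >= z_l)
      Wjl <- Pj[, l] - Pj[, j] * Pj[, l]
      Vjl <- XtWXinv[[j]] %*% crossprod(X1, X1 * Wjl) %*% XtWXinv[[l]]
    }
    blk <- Vjl[-1, -1, drop = FALSE]
    ri <- (j - 1) * m + seq_len(m)
    ci <- (l - 1) * m + seq_len(m)
    V[ri, ci] <- blk
    V[ci, ri] <- t(blk)
  }
  bvec <- as.vector(t(betas))            # stacked by cutpoint
  # contrasts: slope_t at cutpoint 1 minus at cutpoints 2..nc, per term
  Drow <- function(tm, j) {
    r <- numeric(nc * m)
    r[tm] <- 1
    r[(j - 1) * m + tm] <- r[(j - 1) * m + tm] - 1
    r
  }
  D <- do.call(rbind, lapply(seq_len(m), function(tm)
    do.call(rbind, lapply(2:nc, function(j) Drow(tm, j)))))
  dB <- D %*% bvec
  chi2 <- drop(t(dB) %*% solve(D %*% V %*% t(D)) %*% dB)
  df <- as.integer(m * (J - 2))
  per_term <- lapply(seq_len(m), function(tm) {
    Dt <- do.call(rbind, lapply(2:nc, function(j) Drow(tm, j)))
    dBt <- Dt %*% bvec
    ct <- drop(t(dBt) %*% solve(Dt %*% V %*% t(Dt)) %*% dBt)
    c(chi2 = ct, df = J - 2,
      p = stats::pchisq(ct, J - 2, lower.tail = FALSE))
  })
  breakdown <- as.data.frame(do.call(rbind, per_term))
  breakdown <- cbind(term = colnames(X), breakdown)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       breakdown = breakdown)
}

#' Ordinal conditional margins: per-category arm contrasts
#'
#' At each score level, the treated-minus-control contrast of every
#' category probability, with delta-method confidence intervals (numerical
#' gradient of the category probabilities in the model parameters).
#' Contrasts across categories sum to zero at every level.
#'
#' @param fit A `gologit` fit of the outcome on a treatment indicator and a
#'   score.
#' @param levels Score values.
#' @param treat,score Term names.
#' @param level Confidence level.
#' @return Data frame with `level`, `category`, `contrast`, `se`, `low`,
#'   `high`.
#' @export
ordinal_margins <- function(fit, levels, treat = "arm", score = NULL,
                            level = 0.95) {
  stopifnot(inherits(fit, "gologit"))
  if (is.null(score)) {
    nm <- setdiff(colnames(fit$X), treat)
    if (length(nm) != 1) stop("cannot infer score term; pass `score`")
    score <- nm
  }
  J <- length(fit$categories)
  z <- stats::qnorm(1 - (1 - level) / 2)
  theta_hat <- fit$par
  contrast_fun <- function(theta, lev) {
    obj <- fit
    # rebuild alpha/B from theta using the fit's layout
    nc <- J - 1
    obj$thresholds[] <- theta[seq_len(nc)]
    pos <- nc
    B <- obj$coefficients
    for (tm in obj$constraint_map$shared) {
      pos <- pos + 1
      B[, tm] <- theta[pos]
    }
    for (tm in obj$constraint_map$relaxed) {
      B[, tm] <- theta[pos + seq_len(nc)]
      pos <- pos + nc
    }
    obj$coefficients <- B
    nd <- stats::setNames(data.frame(c(1, 0), c(lev, lev)), c(treat, score))
    P <- predict.gologit(obj, nd)
    P[1, ] - P[2, ]
  }
  rows <- lapply(levels, function(lev) {
    c0 <- contrast_fun(theta_hat, lev)
    # central finite-difference Jacobian
    h <- pmax(1e-5, 1e-5 * abs(theta_hat))
    Jac <- vapply(seq_along(theta_hat), function(i) {
      tp <- theta_hat; tp[i] <- tp[i] + h[i]
      tm <- theta_hat; tm[i] <- tm[i] - h[i]
      (contrast_fun(tp, lev) - contrast_fun(tm, lev)) / (2 * h[i])
    }, numeric(J))
    se <- sqrt(pmax(0, diag(Jac %*% fit$vcov %*% t(Jac))))
    data.frame(level = lev, category = fit$categories,
               contrast = c0, se = se,
               low = c0 - z * se, high = c0 + z * se)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
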