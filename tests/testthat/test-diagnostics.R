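test_that("link test reproduces the published specification p-value", {
  expect_equal(round(link_test(fit_sht)$p, 3), 0.127)
})

test_that("link test is calibrated under a correct model and powered under
           a quadratic one", {
  set.seed(10)
  rej <- 0
  for (i in 1:100) {
    x <- rnorm(600)
    y <- rbinom(600, 1, plogis(-0.5 + 0.8 * x))
    f <- fit_logit(y ~ x, data.frame(x = x, y = y))
    if (link_test(f)$p < 0.05) rej <- rej + 1
  }
  # binomial(100, 0.05): mean 5, 2 MC SE ~ 4.4
  expect_lt(rej, 12)
  set.seed(11)
  x <- rnorm(20000)
  y <- rbinom(20000, 1, plogis(-0.5 + 0.5 * x + 0.6 * x^2))
  f <- fit_logit(y ~ x, data.frame(x = x, y = y))
  expect_lt(link_test(f)$p, 0.001)
})

test_that("Box-Tidwell runs with the zero-shift and reports it", {
  bt <- box_tidwell_test(fit_sht, "hti")
  expect_named(bt$p, "hti")
  expect_identical(unname(bt$shift["hti"]), 1)
  expect_gt(bt$p["hti"], 0.05)   # near-linear in the logit on the fixture
})

test_that("Box-Tidwell keeps size under linearity and detects log shape", {
  set.seed(12)
  ok <- 0
  for (i in 1:100) {
    x <- runif(500, 1, 10)
    y <- rbinom(500, 1, plogis(-2 + 0.4 * x))
    f <- fit_logit(y ~ x, data.frame(x = x, y = y))
    if (box_tidwell_test(f, "x")$p["x"] > 0.05) ok <- ok + 1
  }
  expect_gte(ok, 90)
  set.seed(13)
  x <- runif(20000, 1, 20)
  y <- rbinom(20000, 1, plogis(-3 + 2.4 * log(x)))
  f <- fit_logit(y ~ x, data.frame(x = x, y = y))
  expect_lt(box_tidwell_test(f, "x")$p["x"], 0.01)
})

test_that("Hosmer-Lemeshow reproduces the published fixture statistic", {
  hl <- hosmer_lemeshow(fit_sht, groups = 10)
  expect_identical(hl$groups, 8L)
  expect_identical(hl$df, 6L)
  expect_equal(round(hl$chi2, 2), 4.17)
  expect_equal(round(hl$p, 3), 0.654)
})

test_that("Hosmer-Lemeshow statistic is near its df under calibration", {
  set.seed(14)
  chis <- replicate(40, {
    x <- rnorm(2000)
    y <- rbinom(2000, 1, plogis(-1 + x))
    hosmer_lemeshow(fit_logit(y ~ x, data.frame(x = x, y = y)))$chi2
  })
  # mean of a chi-square(8) is 8; allow 3 SEs of the replicate mean
  expect_lt(abs(mean(chis) - 8), 3 * sd(chis) / sqrt(40))
})

test_that("variance inflation factors match a direct R-squared computation", {
  set.seed(15)
  n <- 300
  z <- rnorm(n)
  X <- data.frame(a = z + rnorm(n), b = z + rnorm(n), c = rnorm(n))
  v <- variance_inflation(X)
  for (j in 1:3) {
    r2 <- summary(lm(X[[j]] ~ as.matrix(X[-j])))$r.squared
    expect_equal(unname(v$vif[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
  # orthogonal designs give VIF 1, duplicated terms are flagged infinite
  o <- data.frame(a = rep(c(-1, 1), 50), b = rep(c(-1, -1, 1, 1), 25))
  expect_equal(unname(variance_inflation(o)$vif), c(1, 1), tolerance = 1e-10)
  dup <- data.frame(a = rnorm(50))
  dup$b <- dup$a
  expect_true(is.infinite(variance_inflation(dup)$vif["b"]))
})

test_that("pseudo R-squared reproduces the published fixture values", {
  pr <- pseudo_r2(fit_sht)
  expect_equal(round(pr$mcfadden, 3), 0.186)
  expect_equal(round(pr$cox_snell, 3), 0.102)
  expect_equal(round(pr$nagelkerke, 3), 0.232)
  # the null model explains nothing
  d <- data.frame(y = rep(c(0, 1), 50), x = 1)
  f0 <- fit_logit(y ~ 1, d)
  expect_equal(pseudo_r2(f0)$mcfadden, 0, tolerance = 1e-10)
  expect_equal(pseudo_r2(f0)$nagelkerke, 0, tolerance = 1e-8)
})

test_that("information criteria reproduce the published fixture values", {
  ic <- info_criteria(fit_sht)
  expect_equal(round(ic$aic, 2), 117.78)
  expect_equal(round(ic$bic, 2), 128.20)
  expect_equal(round(fit_sht$deviance, 2), 111.78)
  # algebraic identity on any fit
  expect_equal(ic$bic - ic$aic, ic$k * (log(ic$n) - 2))
})

test_that("likelihood-ratio test reproduces the published model chi-square", {
  f0 <- fit_logit(sht ~ 1, fx_units)
  lr <- lr_test(f0, fit_sht)
  expect_equal(round(lr$chi2, 2), 25.55)
  expect_identical(lr$df, 2L)
  self <- lr_test(fit_sht, fit_sht)
  expect_equal(self$chi2, 0)
  expect_equal(self$p, 1)
  expect_error(lr_test(fit_sht, f0), "not nested")
})

test_that("LR test keeps its size for null extra terms", {
  set.seed(16)
  rej <- 0
  for (i in 1:200) {
    x <- rnorm(300)
    z <- rnorm(300)
    y <- rbinom(300, 1, plogis(-0.5 + x))
    d <- data.frame(x = x, z = z, y = y)
    lr <- lr_test(fit_logit(y ~ x, d), fit_logit(y ~ x + z, d))
    if (lr$p < 0.05) rej <- rej + 1
  }
  # binomial(200, .05): mean 10, 2 MC SE ~ 6.2
  expect_lt(rej, 17)
})

test_that("Romano-Wolf adjustment dominates raw p and controls FWER", {
  # single hypothesis: adjusted equals raw
  set.seed(17)
  tb <- matrix(rnorm(500), ncol = 1)
  rw1 <- romano_wolf_adjust(2.1, tb)
  expect_equal(rw1$adjusted, rw1$raw)
  # dominance for an arbitrary family
  tobs <- c(0.4, 2.5, 1.2, 3.3)
  tb <- matrix(rnorm(4 * 500), ncol = 4)
  rw <- romano_wolf_adjust(tobs, tb)
  expect_true(all(rw$adjusted >= rw$raw - 1e-12))
  # FWER on an all-null family of correlated statistics
  m <- 5
  S <- 0.5 + 0.5 * diag(m)
  L <- chol(S)
  set.seed(18)
  fwe <- 0
  for (i in 1:400) {
    tobs <- drop(rnorm(m) %*% L)
    tb <- matrix(rnorm(300 * m), ncol = m) %*% L
    rw <- romano_wolf_adjust(tobs, tb)
    if (any(rw$adjusted < 0.05)) fwe <- fwe + 1
  }
  # binomial(400, .05): mean 20, 2 MC SE ~ 8.7
  expect_lt(fwe, 29)
})

test_that("bootstrap Romano-Wolf on the model family is reproducible", {
  forms <- list(m_hti = sht ~ arm + hti)
  rw <- rw_treatment_pvalues(fx_units, forms, reps = 120, seed = 5)
  rw2 <- rw_treatment_pvalues(fx_units, forms, reps = 120, seed = 5)
  expect_identical(rw, rw2)
  expect_equal(rw$adjusted, rw$raw)
})

test_that("AUC reproduces the published value and a pairwise oracle", {
  auc <- roc_auc(fit_sht)
  expect_equal(round(auc$auc, 2), 0.83)
  expect_equal(round(auc$ci, 2), c(0.75, 0.90), tolerance = 0.011)
  # brute force over all event/non-event pairs on a small sample
  set.seed(19)
  d <- data.frame(x = rnorm(40))
  d$y <- rbinom(40, 1, plogis(d$x))
  f <- fit_logit(y ~ x, d)
  p1 <- f$fitted[d$y == 1]
  p0 <- f$fitted[d$y == 0]
  brute <- mean(outer(p1, p0, ">") + 0.5 * outer(p1, p0, "=="))
  expect_equal(roc_auc(f)$auc, brute, tolerance = 1e-10)
  # a constant predictor cannot discriminate
  fc <- f
  fc$fitted <- rep(0.5, 40)
  expect_equal(roc_auc(fc)$auc, 0.5)
})

test_that("correlated AUC comparison detects a real difference and not itself", {
  self <- compare_auc(fit_sht, fit_sht)
  expect_equal(self$chi2, 0)
  expect_equal(self$p, 1)
  set.seed(20)
  n <- 2000
  good <- rnorm(n)
  weak <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.6 * good))
  d <- data.frame(good = good, weak = weak, y = y)
  fa <- fit_logit(y ~ good, d)
  fb <- fit_logit(y ~ weak, d)
  expect_lt(compare_auc(fa, fb)$p, 0.001)
  expect_error(compare_auc(fa, fit_sht), "same units")
})

test_that("model ranking is deterministic, order-invariant, and tie-aware", {
  reports <- list(
    hti = postestimation(fit_sht),
    any_ht = postestimation(fit_aht),
    ffo = postestimation(fit_ffo)
  )
  sel <- select_model(reports)
  expect_identical(sel$ranking, sel$criteria$model)
  expect_identical(select_model(rev(reports))$ranking[1], sel$ranking[1])
  tie <- select_model(list(a = reports$hti, b = reports$hti))
  expect_true(tie$tied)
})
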