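# helper: ordinal cohorts from the proportional-odds generator
ord_cohort <- function(n, seed, bt = -0.5, bs = 0.6) {
  cfg <- default_cerehetis_config(n = n, seed = seed)
  cfg$mrs_beta <- c(bt, bs)
  generate_cohort(cfg)
}

test_that("proportional fit recovers generator coefficients at n = 20000", {
  d <- ord_cohort(20000, seed = 30)
  f <- fit_ordered(mrs90 ~ arm + hti, d, mode = "proportional")
  # generator: P(Y <= j) = plogis(cut_j - eta); fit: P(Y > j) = plogis(a_j + xb)
  # so fitted slopes estimate +mrs_beta
  se <- sqrt(diag(f$vcov)[c("arm", "hti")])
  expect_lt(abs(f$coefficients[1, "arm"] - (-0.5)), 3 * se["arm"])
  expect_lt(abs(f$coefficients[1, "hti"] - 0.6), 3 * se["hti"])
})

test_that("proportional fit agrees with an independent ordinal ML routine", {
  skip_if_not_installed("MASS")
  d <- ord_cohort(1500, seed = 31)
  f <- fit_ordered(mrs90 ~ arm + hti, d, mode = "proportional")
  p <- MASS::polr(factor(mrs90) ~ arm + hti, data = d)
  expect_equal(f$loglik, as.numeric(logLik(p)), tolerance = 1e-5)
  # polr parameterizes P(Y <= j) = plogis(zeta_j - x b): same slopes
  expect_equal(unname(f$coefficients[1, ]), unname(coef(p)),
               tolerance = 1e-4)
})

test_that("partial fit with nothing relaxed equals the proportional fit", {
  d <- ord_cohort(800, seed = 32)
  fp <- fit_ordered(mrs90 ~ arm + hti, d, mode = "proportional")
  f0 <- fit_ordered(mrs90 ~ arm + hti, d, mode = "partial",
                    relax = character(0))
  expect_equal(f0$loglik, fp$loglik, tolerance = 1e-6)
})

test_that("partial-proportional log-likelihood dominates the proportional one", {
  d <- ord_cohort(800, seed = 33)
  fp <- fit_ordered(mrs90 ~ arm + hti, d, mode = "proportional")
  fr <- fit_ordered(mrs90 ~ arm + hti, d, mode = "partial", relax = "hti")
  expect_gte(fr$loglik, fp$loglik - 1e-6)
})

test_that("two-category outcome reduces to the binary logit", {
  d <- ord_cohort(1000, seed = 34)
  d$bin <- as.integer(d$mrs90 > 2)
  f <- fit_ordered(bin ~ arm + hti, d, mode = "proportional")
  g <- fit_logit(I(bin == 1) ~ arm + hti, d)
  expect_equal(unname(f$coefficients[1, ]), unname(coef(g)[-1]),
               tolerance = 1e-5)
  expect_equal(unname(f$thresholds[1]), unname(coef(g)[1]),
               tolerance = 1e-5)
})

test_that("category probabilities sum to one at any design point", {
  d <- ord_cohort(800, seed = 35)
  f <- fit_ordered(mrs90 ~ arm + hti, d, mode = "partial", relax = "hti")
  P <- predict(f, data.frame(arm = c(0, 1, 1), hti = c(0, 2, 4)))
  expect_equal(unname(rowSums(P)), rep(1, 3), tolerance = 1e-12)
  expect_true(all(P >= 0))
})

test_that("Brant test has the published structural df and correct size", {
  d <- ord_cohort(3000, seed = 36)
  f <- fit_ordered(mrs90 ~ arm + hti, d, mode = "proportional")
  stopifnot(length(f$categories) == 7)
  b <- brant_test(f)
  expect_identical(b$df, 2L * 5L)      # 2 predictors, 7 categories
  expect_identical(nrow(b$breakdown), 2L)
  expect_true(all(b$breakdown$df == 5))

  # size under proportional odds
  set.seed(37)
  rej <- 0
  nrep <- 60
  for (i in seq_len(nrep)) {
    di <- ord_cohort(700, seed = 4000 + i)
    fi <- tryCatch(fit_ordered(mrs90 ~ arm + hti, di, "proportional"),
                   error = function(e) NULL)
    if (is.null(fi) || length(fi$categories) < 3) next
    p <- tryCatch(brant_test(fi)$p, error = function(e) NA)
    if (!is.na(p) && p < 0.05) rej <- rej + 1
  }
  # binomial(60, .05): mean 3, 2 MC SE ~ 3.4
  expect_lt(rej, 8)
})

test_that("Brant test rejects strongly non-parallel data", {
  # cutpoint-specific slopes: generate from a non-proportional model
  set.seed(38)
  n <- 5000
  x <- runif(n, 0, 4)
  arm <- rbinom(n, 1, 0.5)
  # category via two very different latent mechanisms
  p_gt0 <- plogis(1.5 + 1.2 * x - 0.2 * arm)
  p_gt1 <- plogis(-1.0 - 0.8 * x - 0.2 * arm)
  y <- integer(n)
  u1 <- runif(n) < p_gt0
  u2 <- runif(n) < p_gt1 / pmax(p_gt0, 1e-9)
  y[u1] <- 1L
  y[u1 & u2] <- 2L
  d <- data.frame(y = y, x = x, arm = arm)
  f <- fit_ordered(y ~ x + arm, d, mode = "proportional")
  expect_lt(brant_test(f)$p, 0.01)
})

test_that("Brant statistic is invariant to order-preserving relabeling", {
  d <- ord_cohort(1200, seed = 39)
  f1 <- fit_ordered(mrs90 ~ arm + hti, d, "proportional")
  d$relab <- c(0, 10, 20, 35, 40, 55, 66)[d$mrs90 + 1]
  f2 <- fit_ordered(relab ~ arm + hti, d, "proportional")
  expect_equal(brant_test(f1)$chi2, brant_test(f2)$chi2, tolerance = 1e-6)
})

test_that("ordinal margins contrast to zero across categories and match
           direct evaluation", {
  d <- ord_cohort(1500, seed = 40)
  f <- fit_ordered(mrs90 ~ arm + hti, d, "proportional")
  m <- ordinal_margins(f, levels = c(0, 2))
  sums <- tapply(m$contrast, m$level, sum)
  expect_equal(as.numeric(sums), c(0, 0), tolerance = 1e-10)
  # direct evaluation oracle at level 2
  P1 <- predict(f, data.frame(arm = 1, hti = 2))
  P0 <- predict(f, data.frame(arm = 0, hti = 2))
  expect_equal(m$contrast[m$level == 2], drop(P1 - P0), tolerance = 1e-8,
               ignore_attr = TRUE)
  # zero treatment coefficient: all contrasts vanish
  f0 <- f
  f0$coefficients[, "arm"] <- 0
  f0$par["arm"] <- 0
  m0 <- ordinal_margins(f0, levels = 1)
  expect_equal(m0$contrast, rep(0, 7), tolerance = 1e-10)
})
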