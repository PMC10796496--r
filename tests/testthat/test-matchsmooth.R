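test_that("rule-of-thumb bandwidth: scale equivariance, rate, closed form", {
  set.seed(60)
  x <- rnorm(1000)
  h <- rule_of_thumb_bandwidth(x)
  # closed form with sd ~ 1
  expect_lt(abs(h - 2.34 * min(sd(x), IQR(x) / 1.349) * 1000^(-0.2)), 1e-12)
  expect_lt(abs(h / (2.34 * 1000^(-0.2)) - 1), 0.1)
  # scale equivariance
  expect_equal(rule_of_thumb_bandwidth(5 * x), 5 * h, tolerance = 1e-12,
               ignore_attr = TRUE)
  # doubling n shrinks h by 2^(-1/5)
  x2 <- rep(x, 2)
  expect_equal(rule_of_thumb_bandwidth(x2),
               2^(-1 / 5) * 2.34 * min(sd(x2), IQR(x2) / 1.349) *
                 1000^(-1 / 5),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(rule_of_thumb_bandwidth(rep(3, 10)), "identical")
})

test_that("unit effects: constant outcomes, symmetric pair, recovery", {
  d <- data.frame(arm = rep(0:1, each = 10), y = 0.7, hti = rep(0:4, 4))
  pm <- estimate_propensity(d, "hti")
  ut <- unit_treatment_effects(d, pm, "y", bandwidth = 1)
  expect_equal(ut$d, rep(0, 20))

  # two units with a common index: both see the same contrast
  d2 <- data.frame(arm = c(1, 0), y = c(1, 0))
  pm2 <- structure(list(index = c(0.3, 0.3), score = plogis(c(0.3, 0.3))),
                   class = "propensity")
  ut2 <- unit_treatment_effects(d2, pm2, "y", bandwidth = 0.5)
  expect_equal(ut2$d, c(1, 1))

  # homogeneous risk difference recovered on a randomized cohort: the mRS
  # model drives FFO, with no score effect and a constant treatment shift
  cfg <- default_cerehetis_config(n = 4000)
  cfg$mrs_beta <- c(-0.4, 0)
  d3 <- generate_cohort(cfg, seed = 61)
  pm3 <- estimate_propensity(d3, "hti")
  ut3 <- suppressMessages(unit_treatment_effects(d3, pm3, "ffo"))
  cut3 <- cfg$mrs_cutpoints[3]
  true_rd <- plogis(cut3 + 0.4) - plogis(cut3)
  mc_se <- sd(ut3$d) / sqrt(nrow(d3))
  expect_lt(abs(mean(ut3$d) - true_rd), 6 * mc_se)
})

test_that("local-linear smoothing: constancy, linear exactness, WLS oracle", {
  set.seed(62)
  x <- runif(60, -1, 1)
  # constant effects give a constant curve at any bandwidth
  cv <- smooth_te(rep(0.3, 60), x, bandwidth = 0.2,
                  grid = seq(-0.8, 0.8, length.out = 9))
  expect_equal(cv$te, rep(0.3, nrow(cv)), tolerance = 1e-10)
  # degree-1 fits reproduce a line exactly
  d <- 0.5 - 1.2 * x
  cv2 <- smooth_te(d, x, bandwidth = 50, grid = c(-0.5, 0, 0.5))
  expect_equal(cv2$te, 0.5 - 1.2 * cv2$grid, tolerance = 1e-10)
  # interior point matches a hand-assembled weighted regression
  dn <- d + rnorm(60, sd = 0.1)
  h <- 0.4
  x0 <- 0.1
  cv3 <- smooth_te(dn, x, bandwidth = h, grid = x0)
  w <- ifelse(abs((x - x0) / h) < 1, 0.75 * (1 - ((x - x0) / h)^2), 0)
  b <- coef(lm(dn ~ I(x - x0), weights = w))
  expect_equal(cv3$te, unname(b[1]), tolerance = 1e-10)
  # bands contain the point estimate
  expect_true(all(cv3$ci_low <= cv3$te & cv3$te <= cv3$ci_high))
})

test_that("score-level effects equal the matched ATE when the index is flat", {
  set.seed(63)
  d <- data.frame(arm = rep(0:1, each = 60), y = rbinom(120, 1, 0.35))
  pm <- structure(list(index = rep(0.2, 120), score = rep(plogis(0.2), 120)),
                  class = "propensity")
  ut <- unit_treatment_effects(d, pm, "y", bandwidth = 1)
  cv <- smooth_te(ut$d, ut$index + rnorm(120, sd = 1e-9), bandwidth = 1,
                  grid = 0.2)
  sc <- score_level_effects(cv, c("0" = 0.2))
  ate <- mean(ut$d)
  expect_equal(sc$te, ate, tolerance = 1e-6)
})

test_that("p-values follow the z-score of the interval by construction", {
  set.seed(64)
  x <- rnorm(100)
  d <- 0.1 * x + rnorm(100, sd = 0.3)
  cv <- smooth_te(d, x, bandwidth = 2)
  sc <- score_level_effects(cv, c("0" = -0.5, "1" = 0.5))
  z <- sc$te * 2 * qnorm(0.975) / (sc$ci_high - sc$ci_low)
  expect_equal(sc$p, 2 * pnorm(-abs(z)), tolerance = 1e-10)
  expect_error(score_level_effects(cv, c("0" = 99)), "outside")
})

test_that("the full analysis is deterministic under a fixed seed", {
  h1 <- hte_matchsmooth(fx_units, "sht", reps = 60, seed = 9)
  h2 <- hte_matchsmooth(fx_units, "sht", reps = 60, seed = 9)
  expect_identical(h1$score_effects, h2$score_effects)
  expect_identical(h1$curve$te, h2$curve$te)
})

test_that("fixture propensity column reproduces the published index values", {
  h <- hte_matchsmooth(fx_units, "sht", ci = "analytic")
  expect_equal(round(h$score_effects$propensity, 3),
               c(-0.486, -0.479, -0.473, -0.466, -0.460))
})

test_that("complement symmetry: FFO curve mirrors the poor-outcome curve", {
  d <- fx_units
  d$poor <- 1L - d$ffo
  h1 <- hte_matchsmooth(d, "ffo", ci = "analytic")
  h2 <- hte_matchsmooth(d, "poor", ci = "analytic")
  expect_equal(h1$score_effects$te, -h2$score_effects$te, tolerance = 1e-10)
})

test_that("smoothed fixture effects are monotone for every outcome", {
  for (o in c("sht", "any_ht")) {
    h <- hte_matchsmooth(fx_units, o, ci = "analytic")
    expect_true(all(diff(h$score_effects$te) < 0))
  }
  h <- hte_matchsmooth(fx_units, "ffo", ci = "analytic")
  expect_true(all(diff(h$score_effects$te) > 0))
})

test_that("methods behave: predict re-fits exactly, coef names scores", {
  h <- hte_matchsmooth(fx_units, "sht", ci = "analytic")
  pr <- predict(h, h$score_effects$propensity)
  expect_equal(pr$te, h$score_effects$te, tolerance = 1e-12)
  expect_named(coef(h), paste0("score", 0:4))
  expect_output(print(h), "Matching-smoothing")
})
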