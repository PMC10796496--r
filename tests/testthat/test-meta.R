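studies_aht <- suppressMessages(make_studies(fx_grouped, "any_ht"))

test_that("study rows: fixture gives 4 strata over 236 subjects with
           hand-computed risk differences", {
  expect_identical(nrow(studies_aht), 4L)
  expect_identical(sum(studies_aht$n1 + studies_aht$n0), 236L)
  p1 <- c(2, 6, 4, 3) / c(34, 34, 17, 6)
  p0 <- c(5, 11, 13, 7) / c(67, 37, 30, 11)
  expect_equal(studies_aht$effect, p1 - p0)
  expect_equal(studies_aht$variance,
               p1 * (1 - p1) / c(34, 34, 17, 6) +
                 p0 * (1 - p0) / c(67, 37, 30, 11))
  expect_message(make_studies(fx_grouped, "any_ht"), "dropped")
  kept <- make_studies(fx_grouped, "any_ht", drop_empty_arm = FALSE)
  expect_identical(nrow(kept), 5L)
})

test_that("Mantel-Haenszel pooled RD equals the hand-computed weighted mean", {
  res <- mh_fixed_rd(studies_aht)
  w <- with(studies_aht, n1 * n0 / (n1 + n0))
  expect_equal(res$pooled,
               sum(w * studies_aht$effect) / sum(w), tolerance = 1e-10)
  # identical risks pool to zero
  eq <- structure(data.frame(label = 1:3, n1 = c(20, 30, 40),
                             e1 = c(4, 6, 8), n0 = c(20, 30, 40),
                             e0 = c(4, 6, 8)),
                  measure = "RD", class = c("study_rows", "data.frame"))
  eq$effect <- 0
  eq$variance <- with(eq, (e1 / n1) * (1 - e1 / n1) * (1 / n1 + 1 / n0))
  expect_equal(mh_fixed_rd(eq)$pooled, 0)
  # a single study pools to itself
  one <- studies_aht[2, , drop = FALSE]
  class(one) <- class(studies_aht)
  attr(one, "measure") <- "RD"
  expect_equal(mh_fixed_rd(one)$pooled, one$effect, tolerance = 1e-10)
})

test_that("Hedges g matches the small-sample formula and pools convexly", {
  d <- data.frame(arm = c(1, 1, 0, 0), y = c(1.5, 0.5, 0.5, -0.5),
                  hti = 0)
  st <- make_studies_smd(d, "y", score = "hti")
  # n1 = n0 = 2, means 1 and 0, sds sqrt(0.5): J = 1 - 3/(4*2 - 1)
  sp <- sqrt(0.5)
  g_hand <- (1 - 3 / (4 * 2 - 1)) * (1 / sp)
  expect_equal(st$effect, g_hand, tolerance = 1e-10)
  # equal means give g = 0
  d0 <- data.frame(arm = rep(c(1, 0), each = 4),
                   y = rep(c(1, 2, 3, 4), 2), hti = 0)
  expect_equal(make_studies_smd(d0, "y")$effect, 0)
  # pooled fixed-effects estimate lies inside the study range
  cfg <- default_cerehetis_config(n = 600)
  ds <- generate_cohort(cfg, seed = 70)
  sts <- suppressMessages(make_studies_smd(ds, "mrs90"))
  res <- iv_fixed_smd(sts)
  expect_gte(res$pooled, min(sts$effect))
  expect_lte(res$pooled, max(sts$effect))
})

test_that("REML reproduces the published any-HT heterogeneity", {
  res <- reml_random(studies_aht)
  expect_equal(res$i2, 10.9, tolerance = 0.5)
  expect_equal(res$h2, 1.12, tolerance = 0.02)
})

test_that("REML tau-squared maximizes the restricted likelihood", {
  res <- reml_random(studies_aht)
  yi <- studies_aht$effect
  vi <- studies_aht$variance
  restll <- function(t2) {
    w <- 1 / (vi + t2)
    mu <- sum(w * yi) / sum(w)
    -0.5 * sum(log(vi + t2)) - 0.5 * log(sum(w)) -
      0.5 * sum(w * (yi - mu)^2)
  }
  grid <- seq(0, 0.05, by = 1e-5)
  t2_grid <- grid[which.max(vapply(grid, restll, numeric(1)))]
  expect_lt(abs(res$tau2 - t2_grid), 2e-5)
})

test_that("degenerate-heterogeneity inputs give tau2 = 0 and match fixed
           effects", {
  same <- structure(data.frame(label = 1:4, n1 = 50, e1 = 10, n0 = 50,
                               e0 = 10, effect = 0.02,
                               variance = 0.004),
                    measure = "RD", class = c("study_rows", "data.frame"))
  res <- reml_random(same)
  expect_equal(res$tau2, 0, tolerance = 1e-10)
  expect_equal(res$i2, 0, tolerance = 1e-8)
  # with tau2 = 0 the REML pooled estimate is the fixed IV estimate
  w <- 1 / same$variance
  expect_equal(res$pooled, sum(w * same$effect) / sum(w), tolerance = 1e-8)
})

test_that("heterogeneity identity I2 = 100 (1 - 1/H2) holds everywhere", {
  for (o in c("sht", "any_ht", "ffo")) {
    st <- suppressMessages(make_studies(fx_grouped, o))
    for (res in list(reml_random(st), mh_fixed_rd(st))) {
      if (res$h2 > 1)
        expect_equal(res$i2, 100 * (1 - 1 / res$h2), tolerance = 1e-6)
    }
  }
})

test_that("fixed-effects pooling is invariant to study order", {
  perm <- studies_aht[c(3, 1, 4, 2), ]
  class(perm) <- class(studies_aht)
  attr(perm, "measure") <- "RD"
  expect_equal(mh_fixed_rd(perm)$pooled, mh_fixed_rd(studies_aht)$pooled,
               tolerance = 1e-12)
})

test_that("Egger test: published null result, size, and preconditions", {
  expect_gt(suppressWarnings(egger_test(studies_aht))$p, 0.05)
  set.seed(71)
  rej <- 0
  for (i in 1:200) {
    k <- 20
    vi <- runif(k, 0.01, 0.2)
    yi <- rnorm(k, 0.1, sqrt(vi))
    st <- structure(data.frame(label = 1:k, n1 = 10, e1 = 1, n0 = 10,
                               e0 = 1, effect = yi, variance = vi),
                    measure = "RD", class = c("study_rows", "data.frame"))
    if (egger_test(st)$p < 0.05) rej <- rej + 1
  }
  # binomial(200, .05): mean 10, 2 MC SE ~ 6.2
  expect_lt(rej, 17)
  two <- studies_aht[1:2, ]
  class(two) <- class(studies_aht)
  attr(two, "measure") <- "RD"
  expect_error(egger_test(two), "at least 3")
})

test_that("forest data: weights sum to 100 and follow the random-effects
           weighting", {
  res <- reml_random(studies_aht)
  fd <- forest_data(res)
  expect_equal(sum(fd$weight[fd$label != "pooled"]), 100, tolerance = 1e-9)
  w <- 1 / (studies_aht$variance + res$tau2)
  expect_equal(fd$weight[fd$label != "pooled"], 100 * w / sum(w),
               tolerance = 1e-10)
  one <- studies_aht[1, ]
  class(one) <- class(studies_aht)
  attr(one, "measure") <- "RD"
  fd1 <- forest_data(mh_fixed_rd(one))
  expect_equal(fd1$weight[1], 100)
})
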