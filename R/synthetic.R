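# Synthetic cohort generator. Emulates the statistical structure the
# analysis chain assumes: per-arm HTI marginal distributions, binary
# outcomes following a treatment + HTI logistic model (symptomatic HT
# drawn hierarchically inside any HT), and an ordinal day-90 mRS from a
# proportional-odds model whose favorable-outcome margin matches the FFO
# logistic model at the reference level. Covariates are back-filled so the
# score calculators reproduce the drawn HTI exactly.

#' Generator configuration
#'
#' Bundles all simulation parameters: cohort size, treatment assignment
#' probability, per-arm HTI stratum probabilities, per-outcome logistic
#' coefficients (intercept, treatment, score, optional score-by-treatment
#' interaction), proportional-odds cutpoints and slopes for mRS, and the
#' seed.
#'
#' @param n Cohort size.
#' @param treat_frac Probability of assignment to the treated arm.
#' @param hti_probs List with `treated` and `control` probability vectors
#'   over HTI values 0..(length-1); each must sum to 1.
#' @param beta Named list of coefficient vectors `c(intercept, treatment,
#'   score)` (optionally a 4th interaction term) for outcomes `sht` (on the
#'   any-HT-conditional scale, see [generate_cohort()]), `any_ht`, `ffo`.
#' @param mrs_cutpoints Six strictly increasing cumulative-logit cutpoints
#'   (categories 0-6).
#' @param mrs_beta Coefficients `c(treatment, score)` of the mRS
#'   proportional-odds model (positive = worse outcomes).
#' @param effect_heterogeneity Score-by-treatment interaction added to each
#'   binary outcome's logit (default 0).
#' @param seed Integer seed.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n, treat_frac, hti_probs, beta, mrs_cutpoints,
                             mrs_beta, effect_heterogeneity = 0, seed = 1) {
  stopifnot(n >= 1, treat_frac > 0, treat_frac < 1,
            abs(sum(hti_probs$treated) - 1) < 1e-8,
            abs(sum(hti_probs$control) - 1) < 1e-8,
            all(diff(mrs_cutpoints) > 0),
            length(mrs_cutpoints) == 6,
            all(c("sht", "any_ht", "ffo") %in% names(beta)))
  structure(list(n = n, treat_frac = treat_frac, hti_probs = hti_probs,
                 beta = beta, mrs_cutpoints = mrs_cutpoints,
                 mrs_beta = mrs_beta,
                 effect_heterogeneity = effect_heterogeneity, seed = seed),
            class = "generator_config")
}

#' Default generator configuration calibrated to the fixture
#'
#' Per-arm HTI stratum probabilities are the fixture's empirical per-arm
#' proportions, and the outcome coefficients are obtained by fitting the
#' treatment + HTI logit to the expanded fixture at call time (symptomatic
#' HT, any HT and FFO), not hard-coded. The mRS proportional-odds slopes
#' are the negated FFO slopes and the third cutpoint equals the FFO
#' intercept, so that P(mRS <= 2) from the ordinal model reproduces the
#' FFO logistic model exactly at every design point; the remaining
#' cutpoints are spaced around it to give a realistic spread of disability
#' scores.
#'
#' @param n Cohort size (default 238, the fixture size).
#' @param seed Integer seed.
#' @return A `generator_config`.
#' @export
default_cerehetis_config <- function(n = 238, seed = 1) {
  g <- cerehetis_cohort()
  u <- expand_cohort(g)
  beta <- lapply(c(sht = "sht", any_ht = "any_ht", ffo = "ffo"),
                 function(o) {
                   f <- stats::as.formula(paste(o, "~ arm + hti"))
                   unname(coef(fit_logit(f, u)))
                 })
  n1 <- g$n[g$arm == 1]
  n0 <- g$n[g$arm == 0]
  bf <- beta$ffo
  generator_config(
    n = n, treat_frac = sum(n1) / sum(g$n),
    hti_probs = list(treated = n1 / sum(n1), control = n0 / sum(n0)),
    beta = beta,
    # cutpoint 3 pinned to the FFO intercept; spacing chosen for a
    # plausible mRS spread (documented in the methods vignette)
    mrs_cutpoints = bf[1] + c(-2.2, -1.0, 0, 1.0, 2.2, 3.5),
    mrs_beta = c(-bf[2], -bf[3]),
    seed = seed
  )
}

# valid component decompositions of each HTI value:
# aspects band (0-3) + nihss band (0-3) + hmca (0/1) + af (0/1) = hti
.hti_decompositions <- local({
  combos <- expand.grid(a = 0:3, nb = 0:3, hm = 0:1, af = 0:1)
  split(combos, combos$a + combos$nb + combos$hm + combos$af)
})

# draw covariates consistent with a target HTI value
.backfill_covariates <- function(hti) {
  n <- length(hti)
  a_band <- nihss_band <- hmca <- af <- integer(n)
  for (h in unique(hti)) {
    sel <- which(hti == h)
    pool <- .hti_decompositions[[as.character(h)]]
    pick <- pool[sample.int(nrow(pool), length(sel), replace = TRUE), ]
    a_band[sel] <- pick$a
    nihss_band[sel] <- pick$nb
    hmca[sel] <- pick$hm
    af[sel] <- pick$af
  }
  aspects_lo <- c(7, 5, 3, 0)[a_band + 1]
  aspects_hi <- c(10, 6, 4, 2)[a_band + 1]
  aspects <- aspects_lo +
    floor(stats::runif(n) * (aspects_hi - aspects_lo + 1))
  nihss_lo <- c(0, 12, 18, 24)[nihss_band + 1]
  nihss_hi <- c(11, 17, 23, 42)[nihss_band + 1]
  nihss <- nihss_lo + floor(stats::runif(n) * (nihss_hi - nihss_lo + 1))
  data.frame(aspects = aspects, nihss = nihss, hmca = hmca, af_ecg = af)
}

#' Generate a synthetic cohort
#'
#' Draws treatment Bernoulli(`treat_frac`); the HTI score from the per-arm
#' stratum probabilities; component covariates (ASPECTS, NIHSS, HMCA sign,
#' AF on ECG) uniformly over the decompositions consistent with the drawn
#' HTI, so [compute_hti()] reproduces it exactly; any HT as
#' Bernoulli(invlogit(b0 + b1 arm + b2 hti + b3 arm hti)); symptomatic HT
#' hierarchically inside any HT (the `sht` coefficients describe the
#' marginal sHT logit, and the conditional probability sHT-given-any-HT is
#' their ratio, clipped to 1), enforcing sht <= any_ht record-wise; mRS
#' from the proportional-odds model; `ffo` derived as mrs90 <= 2.
#' Remaining covariates (age, sex, glucose, pre-stroke mRS,
#' onset-to-treatment time) are drawn from plausible stroke-admission
#' distributions independent of HTI.
#'
#' @param config A `generator_config`.
#' @param seed Optional seed overriding `config$seed`.
#' @return Patient-level data frame following [cohort_schema()] plus an
#'   `hti` column.
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  n <- config$n
  arm <- stats::rbinom(n, 1, config$treat_frac)
  K <- length(config$hti_probs$treated)
  hti <- integer(n)
  n1 <- sum(arm == 1)
  hti[arm == 1] <- sample.int(K, n1, replace = TRUE,
                              prob = config$hti_probs$treated) - 1L
  hti[arm == 0] <- sample.int(K, n - n1, replace = TRUE,
                              prob = config$hti_probs$control) - 1L
  cov <- .backfill_covariates(hti)

  linpred <- function(b) {
    b4 <- if (length(b) >= 4) b[4] else config$effect_heterogeneity
    b[1] + b[2] * arm + b[3] * hti + b4 * arm * hti
  }
  p_any <- stats::plogis(linpred(config$beta$any_ht))
  p_sht <- stats::plogis(linpred(config$beta$sht))
  any_ht <- stats::rbinom(n, 1, p_any)
  p_cond <- pmin(1, p_sht / pmax(p_any, 1e-12))
  sht <- any_ht * stats::rbinom(n, 1, p_cond)

  eta <- config$mrs_beta[1] * arm + config$mrs_beta[2] * hti
  u <- stats::runif(n)
  cum <- stats::plogis(outer(-eta, config$mrs_cutpoints, "+")) # P(Y <= j)
  mrs90 <- rowSums(u > cum)               # 0..6
  ffo <- as.integer(mrs90 <= 2)

  d <- data.frame(
    id = sprintf("S%05d", seq_len(n)),
    arm = arm,
    age = pmin(95, pmax(30, round(stats::rnorm(n, 68, 11)))),
    sex = stats::rbinom(n, 1, 0.55),
    nihss = cov$nihss,
    aspects = cov$aspects,
    hmca = cov$hmca,
    af_ecg = cov$af_ecg,
    glucose = round(exp(stats::rnorm(n, log(6.5), 0.25)), 1),
    prestroke_mrs = sample(0:2, n, replace = TRUE, prob = c(0.8, 0.15, 0.05)),
    onset_to_treatment = round(stats::runif(n, 45, 270)),
    sht = sht,
    any_ht = any_ht,
    mrs90 = mrs90,
    ffo = ffo,
    hti = hti
  )
  validate_cohort(d)
  d
}

#' Generate a null cohort (no treatment effect)
#'
#' As [generate_cohort()] with every treatment coefficient (including any
#' interaction and the ordinal treatment slope) forced to zero, and with
#' both arms drawing the HTI score from the pooled stratum distribution,
#' so the arm label is fully ignorable: permuting it leaves the joint
#' distribution of scores and outcomes unchanged. Used for type-I error
#' and familywise-error checks.
#'
#' @inheritParams generate_cohort
#' @return Patient-level data frame.
#' @export
generate_null_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  cfg$beta <- lapply(cfg$beta, function(b) {
    b[2] <- 0
    if (length(b) >= 4) b[4] <- 0
    b
  })
  cfg$effect_heterogeneity <- 0
  cfg$mrs_beta[1] <- 0
  pooled <- cfg$treat_frac * cfg$hti_probs$treated +
    (1 - cfg$treat_frac) * cfg$hti_probs$control
  cfg$hti_probs <- list(treated = pooled, control = pooled)
  generate_cohort(cfg, seed = seed)
}
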