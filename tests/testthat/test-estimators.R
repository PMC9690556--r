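test_that("logistic fits agree with an independent IRLS oracle", {
  fx <- logistic_fixture()
  X <- cbind(1, fx$z, fx$w3, fx$w4)
  beta_oracle <- irls_logistic(X, fx$y)
  fit <- fit_logistic(fx, "y", c("z", "w3", "w4"))
  expect_equal(unname(fit$coefficients), beta_oracle, tolerance = 1e-6)

  est <- lr_or(fx)
  expect_equal(est$or, exp(beta_oracle[2]), tolerance = 1e-6)
  expect_equal(est$ci_low, exp(log(est$or) - 1.96 * est$se_log_or),
               tolerance = 1e-12)
  expect_equal(est$ci_high, exp(log(est$or) + 1.96 * est$se_log_or),
               tolerance = 1e-12)
})

test_that("a response unrelated to the covariates yields a flat fit", {
  set.seed(31)
  n <- 5e4
  d <- tibble::tibble(y = rbinom(n, 1, 0.3), w3 = rnorm(n), w4 = rnorm(n))
  fit <- fit_logistic(d, "y", c("w3", "w4"))
  # intercept score equation: mean fitted equals the response mean exactly
  expect_lt(abs(mean(fit$ps) - mean(d$y)), 1e-8)
  expect_lt(sd(fit$ps), 0.01)
  expect_lt(abs(median(fit$ps) - mean(d$y)), 0.01)
})

test_that("the treatment model uses exactly its specified covariates", {
  co <- generate_cohort(2000, seed = 32)
  pf <- fit_propensity(co)
  expect_identical(names(pf$coefficients), c("(Intercept)", "w2", "w6"))
})

test_that("perfect separation is reported, not silently fitted", {
  d <- tibble::tibble(x = c(-(20:1), 1:20) / 10,
                      y = as.integer(c(rep(0, 20), rep(1, 20))))
  expect_error(fit_logistic(d, "y", "x"), "eparation")
})

test_that("greedy caliper matching reproduces the enumeration oracle", {
  lp <- c(0.0, 1.0, 5.0, 0.1, 1.1)
  z <- c(1L, 1L, 1L, 0L, 0L)
  mult <- 0.5 / sd(lp) # caliper width 0.5 on the logit scale
  m <- match_nearest(lp, z, mult)
  expect_identical(m$n_matched, 2L)
  # the far treated subject (logit 5.0) stays unmatched
  expect_setequal(m$pairs$treated, c(1L, 2L))
  expect_identical(m$pairs$control[m$pairs$treated == 2L], 5L)
  expect_identical(m$pairs$control[m$pairs$treated == 1L], 4L)
  oracle <- greedy_match_oracle(lp, z, 0.5)
  expect_equal(m$pairs$treated, oracle[, 1])
  expect_equal(m$pairs$control, oracle[, 2])
})

test_that("matching with identical arm-wise scores pairs everyone at distance zero", {
  lp <- c(0.2, 0.5, 0.8, 0.2, 0.5, 0.8, 0.9)
  z <- c(1L, 1L, 1L, 0L, 0L, 0L, 0L)
  m <- match_nearest(lp, z, 0.15)
  expect_identical(m$n_matched, 3L)
  expect_true(all(m$pairs$distance == 0))
})

test_that("matching respects the caliper and never reuses a control", {
  set.seed(33)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    lp <- rnorm(n)
    z <- rbinom(n, 1, 0.4)
    if (sum(z) == 0 || sum(z) == n) next
    m <- match_nearest(lp, z, 0.15)
    expect_true(all(m$pairs$distance <= m$caliper_width + 1e-12))
    expect_false(any(duplicated(m$pairs$control)))
    expect_false(any(duplicated(m$pairs$treated)))
    expect_true(all(z[m$pairs$treated] == 1))
    expect_true(all(z[m$pairs$control] == 0))
  }
  expect_error(match_nearest(rep(1, 10), rep(c(0L, 1L), 5)), "Zero variance")
  expect_error(match_nearest(rnorm(5), rep(1L, 5)), "non-empty")
})

test_that("matched-sample odds ratio equals the closed-form 2x2 value", {
  co <- paired_cohort(30, 20, 20, 30)
  est <- ps_matching_or(co, ps_covariates = "w2")
  expect_equal(est$or, or_2x2(30, 20, 20, 30), tolerance = 1e-9) # 2.25
  expect_identical(est$n_used, 100L)

  same <- paired_cohort(25, 25, 25, 25)
  expect_equal(ps_matching_or(same, ps_covariates = "w2")$or, 1,
               tolerance = 1e-9)
})

test_that("propensity adjustment degenerates to the crude fit when the score is flat", {
  set.seed(34)
  n <- 4000
  d <- tibble::tibble(
    w2 = rep(60, n), # constant covariate: fitted propensity is flat
    z = rbinom(n, 1, 0.5), delta = 1L)
  d$y <- rbinom(n, 1, plogis(-1 + 0.5 * d$z))
  adj <- ps_covariate_or(d, ps_covariates = "w2")
  crude <- lr_or(d, covariates = NULL)
  expect_equal(log(adj$or), log(crude$or), tolerance = 1e-10)
})

test_that("IPTW with a flat propensity equals the crude 2x2 odds ratio", {
  set.seed(35)
  n <- 4000
  d <- tibble::tibble(w2 = rep(60, n), z = rbinom(n, 1, 0.4), delta = 1L)
  d$y <- rbinom(n, 1, plogis(-1 + 0.6 * d$z))
  est <- iptw_or(d, ps_covariates = "w2")
  tab <- table(y = d$y, z = d$z)
  expect_equal(est$or, or_2x2(tab["1", "1"], tab["0", "1"],
                              tab["1", "0"], tab["0", "0"]),
               tolerance = 1e-8)
})

test_that("IPTW matches a two-stratum enumeration oracle", {
  # two strata with different treatment probabilities and outcome risks
  counts <- expand.grid(s = 0:1, z = 0:1, y = 0:1)
  counts$n <- c(40, 10, 20, 30, 15, 20, 25, 40)
  d <- counts[rep(seq_len(nrow(counts)), counts$n), c("s", "z", "y")]
  d <- tibble::tibble(w2 = d$s, z = as.integer(d$z), y = as.integer(d$y),
                      delta = 1L)
  # oracle: weight by inverse empirical stratum treatment probability and
  # compare weighted outcome odds between arms
  pz <- tapply(d$z, d$w2, mean)
  w <- ifelse(d$z == 1, 1 / pz[as.character(d$w2)],
              1 / (1 - pz[as.character(d$w2)]))
  p1 <- sum(w * d$z * d$y) / sum(w * d$z)
  p0 <- sum(w * (1 - d$z) * d$y) / sum(w * (1 - d$z))
  oracle_or <- (p1 / (1 - p1)) / (p0 / (1 - p0))
  est <- iptw_or(d, ps_covariates = "w2")
  expect_equal(est$or, oracle_or, tolerance = 1e-8)
})

test_that("estimators are invariant to row order", {
  co <- generate_cohort(3000, seed = 36)
  am <- ampute_outcome(co, "mnar", 0.2, seed = 37)
  perm <- sample(nrow(am))
  shuffled <- am[perm, ]
  for (f in list(lr_or, ps_covariate_or, iptw_or)) {
    expect_equal(f(am)$or, f(shuffled)$or, tolerance = 1e-10)
  }
  expect_equal(ps_matching_or(am)$or, ps_matching_or(shuffled)$or,
               tolerance = 1e-10)
})

test_that("matching on a correctly specified propensity balances the covariates", {
  co <- generate_cohort(5000, seed = 38)
  pf <- fit_propensity(co, covariates = c("w3", "w5", "w6")) # true model
  m <- match_nearest(pf$logit_ps, co$z)
  md <- co[c(m$pairs$treated, m$pairs$control), ]
  for (v in c("w1", "w2", "w3", "w4", "w5", "w6")) {
    expect_lt(smd(md[[v]], md$z), 0.1)
  }
})

test_that("IPTW with the true treatment model recovers the marginal OR", {
  ors <- vapply(1:300, function(r) {
    co <- generate_cohort(5000, seed = 3000 + r)
    iptw_or(co, ps_covariates = c("w3", "w5", "w6"))$or
  }, 0)
  mc_tol <- 3 * sd(ors) / sqrt(length(ors))
  expect_lt(abs(mean(ors) - 1.663), mc_tol + 0.01)
})
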