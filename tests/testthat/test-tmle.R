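test_that("the clever covariate evaluates the weighted signed formula", {
  expect_equal(clever_covariate(1, 0.5, 1, "cc"), 2)
  expect_equal(clever_covariate(0, 0.5, 0.5, "ipw"), -4)
  expect_equal(clever_covariate(1, 0.25, 0.8, "ipw"), 5)
  # cc mode ignores the observation probability
  expect_equal(clever_covariate(1, 0.25, 0.8, "cc"), 4)
  expect_error(clever_covariate(1, 1.2, 1), "out of")
  expect_error(clever_covariate(1, 0.5, 0), "out of")
})

test_that("without targeting the estimate is the G-computation plug-in", {
  co <- generate_cohort(1500, seed = 41)
  fit <- tmle_or(co, library = "glm_main", folds = 5, seed = 42,
                 fluctuate = FALSE)
  q1 <- bound_prob(predict(fit$q_fit, transform(co, z = 1L)),
                   c(5e-4, 1 - 5e-4))
  q0 <- bound_prob(predict(fit$q_fit, transform(co, z = 0L)),
                   c(5e-4, 1 - 5e-4))
  plug_in <- (mean(q1) / (1 - mean(q1))) / (mean(q0) / (1 - mean(q0)))
  expect_equal(fit$estimate$or, plug_in, tolerance = 1e-12)
  expect_identical(unname(fit$components$epsilon), c(0, 0))
})

test_that("saturated TMLE equals the nonparametric cell-frequency plug-in", {
  # one binary covariate; all 8 (w, z, y) cells populated
  cells <- expand.grid(w = 0:1, z = 0:1, y = 0:1)
  cells$n <- c(6, 4, 5, 7, 3, 6, 4, 5)
  d <- cells[rep(seq_len(nrow(cells)), cells$n), c("w", "z", "y")]
  d <- tibble::tibble(w = as.integer(d$w), z = as.integer(d$z),
                      y = as.integer(d$y), delta = 1L)

  # oracle: empirical cell means marginalized over the covariate law
  qhat <- function(zv, wv) {
    sub <- d[d$z == zv & d$w == wv, ]
    mean(sub$y)
  }
  p1 <- mean(ifelse(d$w == 1, qhat(1, 1), qhat(1, 0)))
  p0 <- mean(ifelse(d$w == 1, qhat(0, 1), qhat(0, 0)))
  oracle <- (p1 / (1 - p1)) / (p0 / (1 - p0))

  fit <- tmle_or(d, q_covariates = "w", g_covariates = "w",
                 library = "glm_interactions", missing = "cc", folds = 5,
                 seed = 43)
  expect_equal(fit$estimate$or, oracle, tolerance = 1e-8)
})

test_that("influence-function columns are mean zero after targeting", {
  co <- generate_cohort(4000, seed = 44)
  am <- ampute_outcome(co, "mnar", 0.2, seed = 45)
  for (mode in c("cc", "ipw")) {
    fit <- tmle_or(am, library = "glm_main", missing = mode, folds = 5,
                   seed = 46)
    expect_lt(abs(mean(fit$ic$ic1)), 1e-6)
    expect_lt(abs(mean(fit$ic$ic0)), 1e-6)
  }
})

test_that("the single-epsilon fluctuation solves the combined score equation", {
  co <- generate_cohort(4000, seed = 47)
  am <- ampute_outcome(co, "mnar", 0.2, seed = 48)
  fit <- tmle_or(am, library = "glm_main", missing = "ipw", folds = 5,
                 seed = 49, fluctuation = "one")
  cm <- fit$components
  resid <- ifelse(am$delta == 1L,
                  ifelse(am$z == 1L, am$y - cm$q_star1, am$y - cm$q_star0),
                  0)
  expect_lt(abs(mean(cm$h * resid)), 1e-6)
  # the two parametrizations agree closely on a well-behaved cohort
  fit2 <- tmle_or(am, library = "glm_main", missing = "ipw", folds = 5,
                  seed = 49)
  expect_lt(abs(log(fit$estimate$or) - log(fit2$estimate$or)), 0.05)
})

test_that("EIF standard error tracks a nonparametric bootstrap", {
  co <- generate_cohort(2000, seed = 7)
  fit <- tmle_or(co, library = "glm_main", missing = "cc", folds = 5,
                 seed = 50)
  boot <- vapply(1:400, function(b) {
    set.seed(60000 + b)
    idx <- sample(nrow(co), replace = TRUE)
    log(tmle_or(co[idx, ], library = "glm_main", missing = "cc", folds = 5,
                seed = 50)$estimate$or)
  }, 0)
  expect_lt(abs(fit$estimate$se_log_or - sd(boot)) / sd(boot), 0.25)
})

test_that("nuisance probabilities respect their bounds and rows can be permuted", {
  co <- generate_cohort(3000, seed = 51)
  am <- ampute_outcome(co, "mnar", 0.3, seed = 52)
  fit <- tmle_or(am, library = "glm_main", missing = "ipw", folds = 5,
                 seed = 53, g_bounds = c(0.1, 0.9), q_bounds = c(0.01, 0.99))
  cm <- fit$components
  expect_true(all(cm$g1 >= 0.1 & cm$g1 <= 0.9))
  expect_true(all(cm$q1 >= 0.01 & cm$q1 <= 0.99))
  expect_true(all(cm$d1 >= 0.1 & cm$d1 <= 0.9))

  perm <- sample(nrow(am))
  fit_p <- tmle_or(am[perm, ], library = "glm_main", missing = "ipw",
                   folds = 5, seed = 53, g_bounds = c(0.1, 0.9),
                   q_bounds = c(0.01, 0.99))
  expect_equal(fit_p$estimate$or, fit$estimate$or, tolerance = 1e-10)
})

test_that("degenerate inputs are refused", {
  co <- generate_cohort(500, seed = 54)
  co$delta <- 0L
  expect_error(tmle_or(co, library = "glm_main", folds = 5, seed = 55),
               "observed outcome|constant")
  expect_error(eif_se(list(), numeric(1), 1, 1), "at least 2")
})

test_that("tidy and glance surface the estimate and diagnostics", {
  co <- generate_cohort(1200, seed = 56)
  am <- ampute_outcome(co, "mnar", 0.2, seed = 57)
  fit <- tmle_or(am, library = sl_library("tmle1"), missing = "ipw",
                 folds = 5, seed = 58)
  td <- tidy(fit)
  expect_identical(td$method, "TMLE1 (IPW)")
  expect_true(td$ci_low <= td$or && td$or <= td$ci_high)
  gl <- glance(fit)
  expect_identical(gl$missing_mode, "ipw")
  expect_true(gl$p1 > gl$p0) # protective-to-harmful ordering of this DGP
  # super-learner weight tables for all three nuisance models
  expect_identical(nrow(tidy(fit$q_fit)), 3L)
  expect_identical(nrow(tidy(fit$d_fit)), 3L)
})
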