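sim_logistic_data <- function(n, seed) {
  set.seed(seed)
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rbinom(n, 1, 0.5))
  d$y <- rbinom(n, 1, plogis(-0.5 + 0.8 * d$x1 - 0.6 * d$x2 + 0.4 * d$x3))
  d
}

constant_learner <- function(p = 0.5) {
  sl_learner(
    "constant",
    fit = function(x, y, seed) p,
    predict = function(object, x) rep(object, nrow(x)))
}

failing_learner <- sl_learner(
  "broken",
  fit = function(x, y, seed) stop("boom"),
  predict = function(object, x) rep(0.5, nrow(x)))

true_model_learner <- sl_learner(
  "true_glm",
  fit = function(x, y, seed) {
    dat <- as.data.frame(x); dat$.y <- y
    glm(.y ~ x1 + x2 + x3, family = binomial(), data = dat)
  },
  predict = function(object, x) {
    as.numeric(predict(object, as.data.frame(x), type = "response"))
  })

plain_glm_learner <- sl_learner(
  "plain_glm",
  fit = function(x, y, seed) {
    dat <- as.data.frame(x); dat$.y <- y
    glm(.y ~ ., family = binomial(), data = dat)
  },
  predict = function(object, x) {
    as.numeric(predict(object, as.data.frame(x), type = "response"))
  })

test_that("a single-candidate library gets weight one and is the ensemble", {
  d <- sim_logistic_data(400, 101)
  fit <- sl_fit(d, "y", c("x1", "x2", "x3"), library = "glm_main",
                folds = 5, seed = 1)
  expect_identical(fit$weights, 1)
  manual <- predict(glm(y ~ x1 + x2 + x3, binomial(), d), d,
                    type = "response")
  expect_equal(predict(fit, d), unname(manual), tolerance = 1e-6)
})

test_that("the meta-learner puts its weight on the well-specified candidate", {
  d <- sim_logistic_data(20000, 102)
  fit <- sl_fit(d, "y", c("x1", "x2", "x3"),
                library = list(true_model_learner, constant_learner(0.5)),
                folds = 5, seed = 2)
  expect_gt(fit$weights[1], 0.9)
})

test_that("weights live on the simplex and the ensemble beats every candidate", {
  for (i in 1:30) {
    d <- sim_logistic_data(300, 200 + i)
    fit <- sl_fit(d, "y", c("x1", "x2", "x3"),
                  library = sl_library("tmle1"), folds = 5, seed = i)
    expect_true(all(fit$weights >= 0))
    expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
    expect_lte(fit$ensemble_cv_risk,
               min(fit$cv_risks, na.rm = TRUE) + 0.005)
  }
})

test_that("fits are reproducible from the seed, stochastic learners included", {
  d <- sim_logistic_data(300, 103)
  lib <- c("glm_main", "random_forest", "tree")
  f1 <- sl_fit(d, "y", c("x1", "x2", "x3"), lib, folds = 5, seed = 9)
  f2 <- sl_fit(d, "y", c("x1", "x2", "x3"), lib, folds = 5, seed = 9)
  expect_identical(f1$weights, f2$weights)
  expect_identical(predict(f1, d), predict(f2, d))
})

test_that("duplicating a candidate cannot hurt the ensemble", {
  d <- sim_logistic_data(500, 104)
  base <- sl_fit(d, "y", c("x1", "x2"), c("glm_main", "tree"),
                 folds = 5, seed = 3)
  dup <- sl_fit(d, "y", c("x1", "x2"), c("glm_main", "tree", "glm_main"),
                folds = 5, seed = 3)
  expect_lte(dup$ensemble_cv_risk, base$ensemble_cv_risk + 0.005)
})

test_that("ensemble predictions are the weighted blend of refit candidates", {
  d <- sim_logistic_data(400, 105)
  fit <- sl_fit(d, "y", c("x1", "x2"), sl_library("tmle1"), folds = 5,
                seed = 4)
  manual <- rep(0, nrow(d))
  for (l in seq_along(fit$learners)) {
    if (fit$weights[l] > 0) {
      manual <- manual + fit$weights[l] *
        fit$learners[[l]]$predict(fit$fits[[l]], d[c("x1", "x2")])
    }
  }
  expect_equal(predict(fit, d), manual, tolerance = 1e-12)

  flat <- d; flat$x1 <- 1; flat$x2 <- 1
  expect_equal(length(unique(predict(fit, flat))), 1L)
})

test_that("prediction demands the training columns", {
  d <- sim_logistic_data(200, 106)
  fit <- sl_fit(d, "y", c("x1", "x2"), "glm_main", folds = 5, seed = 5)
  expect_error(predict(fit, d["x1"]), "lacks column")
})

test_that("a failing candidate is dropped gracefully; an all-failed library errors", {
  d <- sim_logistic_data(300, 107)
  expect_warning(
    fit <- sl_fit(d, "y", c("x1", "x2"),
                  library = list(failing_learner, constant_learner(0.3),
                                 plain_glm_learner),
                  folds = 5, seed = 6),
    "failed")
  expect_identical(fit$weights[1], 0)
  expect_true(is.na(fit$cv_risks[1]))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)

  expect_error(
    suppressWarnings(sl_fit(d, "y", c("x1", "x2"),
                            library = list(failing_learner), folds = 5,
                            seed = 7)),
    "All candidate learners failed")
})

test_that("the log-likelihood meta-learner also yields simplex weights", {
  d <- sim_logistic_data(500, 109)
  fit <- sl_fit(d, "y", c("x1", "x2"), sl_library("tmle1"), folds = 5,
                seed = 10, meta = "nnloglik")
  expect_true(all(fit$weights >= 0))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(predict(fit, d) >= 0 & predict(fit, d) <= 1))
})

test_that("tidy and glance expose risks, weights and ensemble diagnostics", {
  d <- sim_logistic_data(300, 108)
  fit <- sl_fit(d, "y", c("x1", "x2"), sl_library("tmle1"), folds = 5,
                seed = 8)
  td <- tidy(fit)
  expect_identical(names(td), c("learner", "cv_risk", "weight"))
  expect_identical(nrow(td), 3L)
  gl <- glance(fit)
  expect_identical(gl$folds, 5)
  expect_identical(gl$n_learners, 3L)
})
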