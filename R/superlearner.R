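# Cross-validated stacking ("super learner") over a library of candidate
# probability learners.  Out-of-fold predictions from each candidate are
# combined by non-negative least squares onto the simplex; candidates are
# then refit on the full data and the ensemble prediction is the weighted
# average of their probabilities.

#' Construct a custom candidate learner
#'
#' A learner is a pair of functions: `fit(x, y, seed)` returning a fitted
#' object, and `predict(object, x)` returning probabilities.  The built-in
#' families (see [sl_library()]) are defined through the same interface, so
#' custom learners mix freely with them in a library.
#'
#' @param name Label used in weight tables.
#' @param fit Function `(x, y, seed)`; `x` is a tibble of covariates, `y` a
#'   0/1 vector.
#' @param predict Function `(object, x)` returning probabilities in `[0, 1]`.
#' @return An `sl_learner` object.
#' @export
sl_learner <- function(name, fit, predict) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  structure(list(name = name, fit = fit, predict = predict),
            class = "sl_learner")
}

# ---- built-in learner families ---------------------------------------------

# continuous = more than two distinct values (the binary covariates and the
# treatment indicator stay linear everywhere, including in the GAM)
is_continuous <- function(v) is.numeric(v) && length(unique(v)) > 2

glm_data <- function(x, y) {
  dat <- as.data.frame(x)
  dat$.y <- y
  dat
}

# Design matrices are built once per fit and logistic coefficients obtained
# straight from glm.fit, which avoids the model-frame overhead of the
# formula interface inside the cross-validation loop.
mm_build <- function(x, interactions = FALSE) {
  fml <- if (interactions && ncol(x) > 1) {
    as.formula(paste0("~ (", paste(names(x), collapse = " + "), ")^2"))
  } else {
    as.formula(paste("~", paste(names(x), collapse = " + ")))
  }
  model.matrix(fml, data = as.data.frame(x))
}

logit_coef <- function(X, y, start = NULL, epsilon = 1e-8) {
  fit <- tryCatch(
    fast_logit_fit(X, as.numeric(y), start, epsilon, 50L),
    error = function(e) NULL)
  if (is.null(fit)) {
    # rank-deficient designs fall back to glm.fit, which aliases columns
    fit <- suppressWarnings(stats::glm.fit(X, y, family = binomial(),
                                    control = list(maxit = 50,
                                                   epsilon = epsilon)))
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    return(list(coef = cf, deviance = fit$deviance))
  }
  list(coef = setNames(as.numeric(fit$coef), colnames(X)),
       deviance = fit$deviance)
}

mm_predict <- function(object, x) {
  X <- mm_build(x, object$interactions)
  X <- X[, names(object$coef), drop = FALSE]
  as.numeric(plogis(X %*% object$coef))
}

fit_glm_mm <- function(x, y, interactions) {
  X <- mm_build(x, interactions)
  structure(c(logit_coef(X, y), list(interactions = interactions)),
            class = "morbench_glm")
}

# Bidirectional stepwise selection by AIC over the columns of the design
# matrix (scope: intercept-only up to the full matrix).  Excluded terms keep
# a zero coefficient so prediction can use the full matrix unchanged.
fit_step_mm <- function(x, y, interactions) {
  X <- mm_build(x, interactions)
  k <- ncol(X)
  incl <- c(TRUE, rep(FALSE, k - 1))
  cur_fit <- logit_coef(X[, incl, drop = FALSE], y)
  # candidate models are scored at a looser IRLS tolerance with coefficients
  # warm-started from the current model; the winner is refit exactly below
  aic_of <- function(sel) {
    start <- setNames(numeric(sum(sel)), colnames(X)[sel])
    common <- intersect(names(start), names(cur_fit$coef))
    start[common] <- cur_fit$coef[common]
    logit_coef(X[, sel, drop = FALSE], y, start = start,
               epsilon = 1e-6)$deviance + 2 * sum(sel)
  }
  cur <- cur_fit$deviance + 2
  repeat {
    best <- NULL
    for (j in seq_len(k)[-1]) {
      cand <- incl
      cand[j] <- !cand[j]
      a <- aic_of(cand)
      if (a < cur - 1e-8) {
        cur <- a
        best <- cand
      }
    }
    if (is.null(best)) break
    incl <- best
    cur_fit <- logit_coef(X[, incl, drop = FALSE], y)
    cur <- cur_fit$deviance + 2 * sum(incl)
  }
  cf <- setNames(numeric(k), colnames(X))
  cf[incl] <- cur_fit$coef
  structure(list(coef = cf, interactions = interactions),
            class = "morbench_glm")
}

builtin_learner <- function(family) {
  switch(
    family,
    glm_main = sl_learner(
      "glm_main",
      function(x, y, seed) fit_glm_mm(x, y, FALSE),
      mm_predict),
    glm_interactions = sl_learner(
      "glm_interactions",
      function(x, y, seed) fit_glm_mm(x, y, TRUE),
      mm_predict),
    glm_step = sl_learner(
      "glm_step",
      function(x, y, seed) fit_step_mm(x, y, FALSE),
      mm_predict),
    glm_step_interactions = sl_learner(
      "glm_step_interactions",
      function(x, y, seed) fit_step_mm(x, y, TRUE),
      mm_predict),
    gam = sl_learner(
      "gam",
      function(x, y, seed) {
        dat <- glm_data(x, y)
        terms <- vapply(names(x), function(nm) {
          if (is_continuous(x[[nm]])) {
            # modest basis, in line with the low-df smooths conventional in
            # super-learner GAM wrappers
            k <- min(5L, length(unique(x[[nm]])) - 1L)
            sprintf("s(%s, k = %d)", nm, max(k, 3L))
          } else nm
        }, "")
        fml <- as.formula(paste(".y ~", paste(terms, collapse = " + ")))
        environment(fml) <- environment()
        mgcv::gam(fml, family = binomial(), data = dat)
      },
      function(object, x) {
        as.numeric(predict(object, newdata = as.data.frame(x),
                           type = "response"))
      }),
    random_forest = sl_learner(
      "random_forest",
      function(x, y, seed) {
        ranger::ranger(
          x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
          probability = TRUE, num.trees = 500, seed = seed,
          num.threads = 1)
      },
      function(object, x) {
        pr <- predict(object, data = as.data.frame(x),
                      num.threads = 1)$predictions
        if ("1" %in% colnames(pr)) as.numeric(pr[, "1"]) else rep(0, nrow(x))
      }),
    tree = sl_learner(
      "tree",
      function(x, y, seed) {
        dat <- glm_data(x, y)
        dat$.y <- factor(dat$.y, levels = c(0, 1))
        set.seed(seed)
        rpart::rpart(.y ~ ., data = dat, method = "class")
      },
      function(object, x) {
        pr <- predict(object, newdata = as.data.frame(x), type = "prob")
        if ("1" %in% colnames(pr)) as.numeric(pr[, "1"]) else rep(0, nrow(x))
      }),
    abort(sprintf("Unknown learner family `%s`.", family))
  )
}

#' Candidate-learner libraries
#'
#' Two preset libraries mirror the two ensemble configurations compared in
#' the simulation study, plus a bare-GLM configuration:
#' * `"tmle1"` — main-terms logistic regression, bidirectional stepwise
#'   (AIC) selection, and main terms with all pairwise interactions.
#' * `"tmle2"` — the above plus stepwise with interactions, a GAM (smooth
#'   terms on continuous covariates), a 500-tree probability random forest,
#'   and a cost-complexity-pruned classification tree.
#' * `"glm"` — main-terms logistic regression only (no ensembling).
#'
#' @param name `"tmle1"`, `"tmle2"` or `"glm"`, or a character vector of
#'   family names to assemble a custom library.
#' @return Character vector of learner family names.
#' @export
sl_library <- function(name = c("tmle1", "tmle2", "glm")) {
  if (length(name) == 1 && name %in% c("tmle1", "tmle2", "glm")) {
    return(switch(name,
      glm = "glm_main",
      tmle1 = c("glm_main", "glm_step", "glm_interactions"),
      tmle2 = c("glm_main", "glm_step", "glm_interactions",
                "glm_step_interactions", "gam", "random_forest", "tree")))
  }
  name
}

as_learner_list <- function(library) {
  if (inherits(library, "sl_learner")) library <- list(library)
  lapply(library, function(l) {
    if (inherits(l, "sl_learner")) l else builtin_learner(l)
  })
}

# Non-negative least squares of y on the out-of-fold prediction matrix,
# normalized to the simplex.  Falls back to the single best candidate when
# NNLS returns the zero vector.
nnls_weights <- function(oof, y, risks) {
  w <- tryCatch(pracma::lsqnonneg(oof, y)$x, error = function(e) NULL)
  if (is.null(w) || sum(w) <= 0) {
    w <- rep(0, ncol(oof))
    w[which.min(risks)] <- 1
  }
  w / sum(w)
}

# Simplex weights minimizing the negative Bernoulli log-likelihood of the
# blended out-of-fold probabilities (optional meta-learner).
nnloglik_weights <- function(oof, y, risks) {
  L <- ncol(oof)
  if (L == 1) return(1)
  obj <- function(theta) {
    w <- exp(c(0, theta)); w <- w / sum(w)
    p <- bound_prob(as.numeric(oof %*% w), c(1e-6, 1 - 1e-6))
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  opt <- stats::optim(rep(0, L - 1), obj, method = "BFGS")
  w <- exp(c(0, opt$par))
  w / sum(w)
}

#' Cross-validated stacking fit
#'
#' V-fold cross-validation produces out-of-fold probability predictions for
#' every candidate in the library; simplex weights are then chosen by
#' non-negative least squares of the outcome on those predictions (squared
#' error is the canonical stacking loss for binary outcomes; a Bernoulli
#' log-likelihood meta-learner is available via `meta = "nnloglik"`).
#' Candidates are finally refit on the full data.  A candidate that fails to
#' fit or predict is dropped with a warning (weight 0); the fit errors only
#' if every candidate fails.
#'
#' @param frame Data frame holding response and covariates.
#' @param response Name of the 0/1 response column.
#' @param covariates Character vector of predictor columns.
#' @param library A library from [sl_library()], a character vector of
#'   family names, or a list of [sl_learner()] objects.
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Integer seed; fold assignment and the stochastic learners
#'   (forest, tree) are seeded from it, so a fit is reproducible.
#' @param meta `"nnls"` (default) or `"nnloglik"` meta-learner.
#' @return An `sl_fit` object; see [predict.sl_fit()], [tidy.sl_fit()].
#' @examples
#' cohort <- generate_cohort(500, seed = 1)
#' fit <- sl_fit(cohort, "y", c("z", "w3", "w4"), sl_library("tmle1"),
#'               folds = 5, seed = 2)
#' tidy(fit)
#' @export
sl_fit <- function(frame, response, covariates,
                   library = sl_library("tmle1"), folds = 10, seed = NULL,
                   meta = c("nnls", "nnloglik")) {
  meta <- match.arg(meta)
  learners <- as_learner_list(library)
  nm <- vapply(learners, `[[`, "", "name")
  y <- frame[[response]]
  check_binary(y, response)
  x <- as_tibble(frame[covariates])
  n <- length(y)
  if (n < 2 * folds) abort("Need at least 2 rows per fold.")
  if (length(unique(y)) < 2) abort("Response is constant; nothing to learn.")
  seed <- seed %||% sample.int(.Machine$integer.max, 1)

  set.seed(derive_seed(seed, 41L))
  fold_id <- sample(rep(seq_len(folds), length.out = n))

  L <- length(learners)
  oof <- matrix(NA_real_, n, L, dimnames = list(NULL, nm))
  failed <- rep(FALSE, L)
  for (l in seq_len(L)) {
    for (v in seq_len(folds)) {
      tr <- fold_id != v
      res <- tryCatch({
        f <- learners[[l]]$fit(x[tr, , drop = FALSE], y[tr],
                               derive_seed(seed, 1000L + v * 100L + l))
        learners[[l]]$predict(f, x[!tr, , drop = FALSE])
      }, error = function(e) e)
      if (inherits(res, "error") || anyNA(res)) {
        failed[l] <- TRUE
        warn(sprintf("Learner `%s` failed in fold %d (%s); weight set to 0.",
                     nm[l], v,
                     if (inherits(res, "error")) conditionMessage(res)
                     else "NA predictions"))
        break
      }
      oof[!tr, l] <- bound_prob(res, c(0, 1))
    }
  }
  if (all(failed)) abort("All candidate learners failed.")

  ok <- !failed
  risks <- rep(NA_real_, L)
  risks[ok] <- colMeans((oof[, ok, drop = FALSE] - y)^2)
  w <- rep(0, L)
  w[ok] <- switch(meta,
    nnls = nnls_weights(oof[, ok, drop = FALSE], y, risks[ok]),
    nnloglik = nnloglik_weights(oof[, ok, drop = FALSE], y, risks[ok]))

  fits <- vector("list", L)
  for (l in which(ok)) {
    fits[[l]] <- tryCatch(
      learners[[l]]$fit(x, y, derive_seed(seed, 2000L + l)),
      error = function(e) NULL)
    if (is.null(fits[[l]])) {
      warn(sprintf("Learner `%s` failed on the full data; weight set to 0.",
                   nm[l]))
      w[l] <- 0
    }
  }
  if (sum(w) <= 0) abort("All candidate learners failed.")
  w <- w / sum(w)

  ens_risk <- mean((as.numeric(oof[, ok, drop = FALSE] %*% w[ok]) - y)^2)
  structure(
    list(learners = learners, names = nm, weights = w, cv_risks = risks,
         ensemble_cv_risk = ens_risk, folds = folds, seed = seed,
         covariates = covariates, response = response, fits = fits),
    class = "sl_fit")
}

#' Predict from a stacking fit
#'
#' Weighted average of the candidate learners' probability predictions;
#' deterministic given the fit.
#'
#' @param object An [sl_fit()] object.
#' @param newdata Data frame containing the training covariate columns.
#' @param ... Unused.
#' @return Probability vector in `[0, 1]`.
#' @export
predict.sl_fit <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$covariates, names(newdata))
  if (length(missing_cols)) {
    abort(sprintf("`newdata` lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(newdata[object$covariates])
  p <- rep(0, nrow(x))
  for (l in which(object$weights > 0)) {
    p <- p + object$weights[l] * object$learners[[l]]$predict(object$fits[[l]], x)
  }
  bound_prob(as.numeric(p), c(0, 1))
}

#' @describeIn sl_fit Per-candidate cross-validated risks and simplex
#'   weights as a tibble.
#' @param x,object An `sl_fit`.
#' @param ... Unused.
#' @export
tidy.sl_fit <- function(x, ...) {
  tibble(learner = x$names, cv_risk = x$cv_risks, weight = x$weights)
}

#' @describeIn sl_fit One-row ensemble summary.
#' @export
glance.sl_fit <- function(x, ...) {
  tibble(folds = x$folds, n_learners = length(x$names),
         n_failed = sum(is.na(x$cv_risks)),
         best_cv_risk = min(x$cv_risks, na.rm = TRUE),
         ensemble_cv_risk = x$ensemble_cv_risk)
}

#' @describeIn sl_fit Bar chart of ensemble weights with cross-validated
#'   risks in the labels.
#' @export
autoplot.sl_fit <- function(object, ...) {
  d <- tidy(object) |>
    mutate(label = sprintf("%s (CV risk %.4f)", .data$learner,
                           .data$cv_risk))
  ggplot(d, aes(x = .data$label, y = .data$weight)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "ensemble weight",
         title = sprintf("Super learner: %s", object$response)) +
    theme_bw()
}

#' @export
print.sl_fit <- function(x, ...) {
  cat(sprintf("Super learner fit (%d folds, response `%s`)\n",
              x$folds, x$response))
  print(tidy(x))
  invisible(x)
}
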