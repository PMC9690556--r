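# Complete-case estimators of the marginal odds ratio: covariate-adjusted
# logistic regression and the three propensity-score methods (adjustment,
# 1:1 caliper matching, IPTW).  All of them drop rows with delta = 0 before
# any model is fitted, which is the usual complete-case pipeline.

# Build y ~ z + ... formulas from covariate lists plus optional pairwise
# interaction terms given as list(c("a", "b"), ...).
build_formula <- function(response, covariates, interactions = NULL) {
  terms <- covariates
  if (length(interactions)) {
    terms <- c(terms, vapply(interactions, paste, "", collapse = ":"))
  }
  if (!length(terms)) terms <- "1"
  as.formula(paste(response, "~", paste(terms, collapse = " + ")))
}

#' Fit a binary logistic model with convergence and separation checks
#'
#' Maximum-likelihood logistic regression via [stats::glm()], wrapped with
#' the diagnostics the simulation harness relies on: non-convergence is an
#' error reporting the iteration count, and (quasi-)complete separation is
#' an error naming the covariate with the exploding coefficient rather than
#' a silently absurd odds ratio.
#'
#' @param frame Data frame with no missing values in the used columns.
#' @param response Name of the binary response column.
#' @param covariates Character vector of main-effect columns.
#' @param interactions Optional list of character pairs, each a pairwise
#'   interaction.
#' @param weights Optional non-negative case weights (fitted as a
#'   quasibinomial so fractional weights do not warn).
#' @return A list with class `logistic_fit`: the `model`, its
#'   `coefficients`, fitted probabilities `ps` and their logits `logit_ps`.
#' @export
fit_logistic <- function(frame, response, covariates, interactions = NULL,
                         weights = NULL) {
  check_binary(frame[[response]], response)
  fml <- build_formula(response, covariates, interactions)
  dat <- as.data.frame(frame)
  fit <- if (is.null(weights)) {
    suppressWarnings(glm(fml, family = binomial(), data = dat,
                         control = list(maxit = 100)))
  } else {
    dat$.w <- weights
    suppressWarnings(glm(fml, family = quasibinomial(), data = dat,
                         weights = .w, control = list(maxit = 100)))
  }
  if (!fit$converged) {
    abort(sprintf("Logistic fit of `%s` did not converge in %d iterations.",
                  response, fit$iter))
  }
  cf <- coef(fit)
  big <- !is.na(cf) & abs(cf) > 15 & names(cf) != "(Intercept)"
  p <- fit$fitted.values
  if (any(big) && (min(p) < 1e-8 || max(p) > 1 - 1e-8)) {
    abort(sprintf("Perfect separation detected for covariate `%s`.",
                  names(cf)[big][which.max(abs(cf[big]))]))
  }
  ps <- as.numeric(p)
  structure(
    list(model = fit, response = response, covariates = covariates,
         coefficients = cf, ps = ps, logit_ps = qlogis(pmin(pmax(ps, 1e-12), 1 - 1e-12))),
    class = "logistic_fit")
}

#' Fit the propensity-score model
#'
#' Logistic regression of the treatment indicator on baseline covariates,
#' `P(Z = 1 | W)`.  A convenience wrapper around [fit_logistic()] with the
#' treatment as response.
#'
#' @inheritParams fit_logistic
#' @param covariates Covariates of the treatment model (the simulation
#'   study's deliberately misspecified default is `w2` and `w6`).
#' @return A `logistic_fit` with per-subject `ps` and `logit_ps`.
#' @export
fit_propensity <- function(frame, covariates = c("w2", "w6"),
                           interactions = NULL) {
  fit_logistic(frame, "z", covariates, interactions)
}

# One EstimateResult row.
estimate_row <- function(method, log_or, se_log_or, n_used) {
  tibble(
    method = method,
    or = exp(log_or),
    se_log_or = se_log_or,
    ci_low = exp(log_or - 1.96 * se_log_or),
    ci_high = exp(log_or + 1.96 * se_log_or),
    n_used = as.integer(n_used)
  )
}

complete_cases <- function(frame) {
  if (!"delta" %in% names(frame)) return(frame)
  frame[frame$delta == 1L, , drop = FALSE]
}

#' Covariate-adjusted logistic regression odds ratio
#'
#' The traditional estimator: logistic regression of the outcome on
#' treatment plus covariates, reporting `exp` of the treatment coefficient.
#' This is a conditional odds ratio used as an approximation to the marginal
#' one; because the odds ratio is non-collapsible the two differ even under
#' correct specification.  Rows with `delta = 0` are dropped (complete-case
#' analysis).
#'
#' @param frame Cohort tibble with `y`, `z`, `delta`.
#' @param covariates Adjustment covariates besides `z` (misspecified
#'   simulation default: `w3`, `w4`).
#' @param interactions Optional pairwise interactions.
#' @return A one-row tibble: `method, or, se_log_or, ci_low, ci_high, n_used`.
#' @examples
#' cohort <- generate_cohort(2000, seed = 1)
#' lr_or(cohort)
#' @export
lr_or <- function(frame, covariates = c("w3", "w4"), interactions = NULL) {
  cc <- complete_cases(frame)
  fit <- fit_logistic(cc, "y", c("z", covariates), interactions)
  sm <- summary(fit$model)$coefficients
  estimate_row("LR", sm["z", "Estimate"], sm["z", "Std. Error"], nrow(cc))
}

#' Propensity-score adjustment odds ratio
#'
#' Logistic regression of the outcome on treatment and the estimated
#' propensity score as a continuous adjustment covariate.  With
#' `outcome_covariates` the analyst's outcome-model covariates are retained
#' alongside the propensity score, the common applied pipeline (and the
#' configuration the simulation harness benchmarks).
#'
#' @inheritParams lr_or
#' @param ps_covariates Covariates of the treatment model.
#' @param outcome_covariates Optional covariates kept in the outcome stage
#'   in addition to `z` (and the propensity score).
#' @return A one-row estimate tibble.
#' @export
ps_covariate_or <- function(frame, ps_covariates = c("w2", "w6"),
                            outcome_covariates = NULL) {
  cc <- complete_cases(frame)
  ps <- fit_propensity(cc, ps_covariates)$ps
  dat <- as.data.frame(cc)
  dat$.ps <- ps
  fml <- build_formula("y", c("z", outcome_covariates, ".ps"))
  fit <- suppressWarnings(glm(fml, family = binomial(), data = dat))
  sm <- summary(fit)$coefficients
  estimate_row("PS covariate", sm["z", "Estimate"], sm["z", "Std. Error"],
               nrow(cc))
}

#' Greedy 1:1 nearest-neighbour caliper matching on the logit propensity
#'
#' Matches each treated subject to the nearest unmatched control on the
#' logit propensity scale, without replacement, within a caliper of
#' `caliper_sd_mult` standard deviations of the pooled logit-propensity
#' distribution (the conventional 0.15-SD caliper by default).  Treated
#' subjects are processed in descending propensity order (ties broken by
#' index) so the result is deterministic; treated subjects with no control
#' inside the caliper are dropped.
#'
#' @param logit_ps Logit propensity scores for all subjects.
#' @param z Binary treatment vector.
#' @param caliper_sd_mult Caliper width in pooled-SD units.
#' @return A list with class `match_result`: `pairs` (tibble of treated and
#'   control row indices with their distance), `caliper_width`, `n_matched`.
#' @export
match_nearest <- function(logit_ps, z, caliper_sd_mult = 0.15) {
  stopifnot(length(logit_ps) == length(z))
  check_binary(z, "z")
  if (!any(z == 1) || !any(z == 0)) {
    abort("Both treatment groups must be non-empty for matching.")
  }
  sdl <- sd(logit_ps)
  if (!is.finite(sdl) || sdl == 0) {
    abort("Zero variance in logit propensity scores; caliper undefined.")
  }
  caliper <- caliper_sd_mult * sdl
  t_idx <- which(z == 1)
  t_idx <- t_idx[order(-logit_ps[t_idx], t_idx)]
  c_idx <- which(z == 0)
  c_lp <- logit_ps[c_idx]
  avail <- rep(TRUE, length(c_idx))
  pairs_t <- integer(0); pairs_c <- integer(0); dist <- double(0)
  for (ti in t_idx) {
    d <- abs(c_lp - logit_ps[ti])
    d[!avail] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= caliper + 1e-12) {
      avail[j] <- FALSE
      pairs_t <- c(pairs_t, ti)
      pairs_c <- c(pairs_c, c_idx[j])
      dist <- c(dist, d[j])
    }
  }
  structure(
    list(pairs = tibble(treated = pairs_t, control = pairs_c,
                        distance = dist),
         caliper_width = caliper, n_matched = length(pairs_t)),
    class = "match_result")
}

#' Propensity-score matching odds ratio
#'
#' Fits the propensity model on complete cases, performs greedy 1:1 caliper
#' matching ([match_nearest()]), then estimates the odds ratio by an
#' unconditional logistic regression of the outcome on treatment within the
#' matched sample (equivalently the 2x2-table odds ratio).
#'
#' @inheritParams ps_covariate_or
#' @param caliper_sd_mult Caliper width in pooled logit-propensity SD units.
#' @param outcome_covariates Optional covariates retained in the matched
#'   outcome model besides `z`.
#' @return A one-row estimate tibble.
#' @export
ps_matching_or <- function(frame, ps_covariates = c("w2", "w6"),
                           caliper_sd_mult = 0.15,
                           outcome_covariates = NULL) {
  cc <- complete_cases(frame)
  pfit <- fit_propensity(cc, ps_covariates)
  m <- match_nearest(pfit$logit_ps, cc$z, caliper_sd_mult)
  idx <- c(m$pairs$treated, m$pairs$control)
  if (m$n_matched < 2) abort("Fewer than 2 matched pairs.")
  md <- cc[idx, ]
  tab <- table(factor(md$y, c(0, 1)), factor(md$z, c(0, 1)))
  if (any(tab == 0)) {
    abort("Degenerate 2x2 cell in the matched sample; odds ratio undefined.")
  }
  fml <- build_formula("y", c("z", outcome_covariates))
  fit <- suppressWarnings(glm(fml, family = binomial(),
                              data = as.data.frame(md)))
  sm <- summary(fit)$coefficients
  estimate_row("PS matching", sm["z", "Estimate"], sm["z", "Std. Error"],
               nrow(md))
}

#' Inverse-probability-of-treatment-weighted odds ratio
#'
#' Weights each subject by the inverse probability of the treatment actually
#' received (`z / ps + (1 - z) / (1 - ps)`, with the propensity truncated to
#' `ps_bounds`) and fits a weighted logistic regression of outcome on
#' treatment.  The standard error of the log odds ratio uses the robust
#' (HC0 sandwich) variance, since model-based standard errors are
#' anti-conservative under weighting.
#'
#' @inheritParams ps_covariate_or
#' @param ps_bounds Truncation bounds for the estimated propensity.
#' @param outcome_covariates Optional covariates retained in the weighted
#'   outcome model besides `z`.
#' @return A one-row estimate tibble.
#' @export
iptw_or <- function(frame, ps_covariates = c("w2", "w6"),
                    ps_bounds = c(0.001, 0.999),
                    outcome_covariates = NULL) {
  cc <- complete_cases(frame)
  ps <- bound_prob(fit_propensity(cc, ps_covariates)$ps, ps_bounds)
  w <- cc$z / ps + (1 - cc$z) / (1 - ps)
  if (any(!is.finite(w))) abort("Non-finite IPTW weight.")
  dat <- as.data.frame(cc)
  dat$.w <- w
  fml <- build_formula("y", c("z", outcome_covariates))
  fit <- suppressWarnings(glm(fml, family = quasibinomial(), data = dat,
                              weights = .w))
  se <- sqrt(diag(sandwich::vcovHC(fit, type = "HC0"))[["z"]])
  estimate_row("IPTW", coef(fit)[["z"]], se, nrow(cc))
}
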