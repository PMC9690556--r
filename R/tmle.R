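# Targeted maximum likelihood estimation of the marginal odds ratio for a
# binary outcome, with optional inverse-probability weighting for missing
# outcomes built into the clever covariate.

#' Clever covariate of the targeting step
#'
#' The score-direction covariate of the logistic fluctuation,
#' `H(Z, W) = [1 / P(Delta = 1 | Z, W)] * [Z / g(W) - (1 - Z) / (1 - g(W))]`
#' with `g(W) = P(Z = 1 | W)`.  Under complete-case (`"cc"`) handling the
#' leading missingness factor is 1.  Probabilities must already be bounded
#' away from 0 and 1 (bounding belongs upstream, where the nuisance models
#' are fitted).
#'
#' @param z Binary treatment vector.
#' @param g1 `P(Z = 1 | W)`, in (0, 1).
#' @param d1 `P(Delta = 1 | Z, W)` at the observed `z`, in (0, 1].
#' @param mode `"ipw"` or `"cc"`.
#' @return Signed clever covariate (positive for treated, negative for
#'   controls).
#' @examples
#' clever_covariate(1, 0.5, 1, "cc")      #  2
#' clever_covariate(0, 0.5, 0.5, "ipw")   # -4
#' @export
clever_covariate <- function(z, g1, d1 = 1, mode = c("ipw", "cc")) {
  mode <- match.arg(mode)
  check_binary(z, "z")
  if (any(g1 <= 0 | g1 >= 1)) abort("`g1` out of (0, 1); bound it upstream.")
  if (any(d1 <= 0 | d1 > 1)) abort("`d1` out of (0, 1]; bound it upstream.")
  w <- if (mode == "ipw") 1 / d1 else rep(1, length(z))
  w * (z / g1 - (1 - z) / (1 - g1))
}

#' Targeted maximum likelihood estimate of the marginal odds ratio
#'
#' Doubly-robust plug-in estimation in four stages:
#'
#' 1. *Initial fits.*  The outcome regression `Q0(Z, W) = E(Y | Z, W,
#'    Delta = 1)` is fit by the super learner on observed-outcome rows
#'    (covariates: `z` plus `q_covariates`); the propensity
#'    `g(W) = P(Z = 1 | W)` on `g_covariates`; and, under `missing = "ipw"`,
#'    the observation model `P(Delta = 1 | Z, W)` on `z` plus
#'    `d_covariates`.  Under `missing = "cc"` rows with missing outcomes are
#'    discarded entirely and the observation probability is 1.
#' 2. *Bounding.*  `g` and the observation probabilities are truncated to
#'    `g_bounds`, `Q0` to `q_bounds`.
#' 3. *Targeting.*  A one-step logistic fluctuation with the observed
#'    outcome, offset `logit Q0` and the clever covariate
#'    ([clever_covariate()]) updates the initial fit:
#'    `logit Q* = logit Q0 + eps * H`.  By default one fluctuation
#'    coefficient is fitted per treatment arm (`fluctuation = "two"`), which
#'    solves each arm's score equation exactly and makes the per-arm
#'    influence-function means vanish; `fluctuation = "one"` fits the single
#'    shared coefficient on the signed covariate instead.
#' 4. *Evaluation.*  Counterfactual means `p1 = mean Q*(1, W)` and
#'    `p0 = mean Q*(0, W)` over all subjects give
#'    `OR = odds(p1) / odds(p0)`; the standard error of the log odds ratio
#'    comes from the efficient influence function ([eif_se()]) and the 95%
#'    interval is Wald-type on the log scale.
#'
#' @param frame Cohort tibble with `y`, `z`, `delta` (a missing `delta`
#'   column is treated as fully observed).
#' @param q_covariates Outcome-model covariates besides `z` (misspecified
#'   simulation default `w3`, `w4`).
#' @param g_covariates Treatment-model covariates (default `w2`, `w6`).
#' @param d_covariates Observation-model covariates besides `z`; defaults to
#'   `q_covariates`.
#' @param library Learner library for all three nuisance fits
#'   ([sl_library()]).
#' @param missing `"ipw"` (weight the clever covariate by the inverse
#'   observation probability) or `"cc"` (drop unobserved rows).
#' @param folds Cross-validation folds for the super learner.
#' @param g_bounds,q_bounds Truncation bounds for the nuisance
#'   probabilities.
#' @param fluctuation `"two"` (per-arm coefficients, default) or `"one"`
#'   (single shared coefficient on the signed covariate).
#' @param fluctuate Set `FALSE` to skip targeting (`eps = 0`), giving the
#'   plain G-computation plug-in of the initial fit.
#' @param seed Integer seed for the super learner.
#' @param meta Meta-learner passed to [sl_fit()].
#' @param label Method label for the estimate row.
#' @return A `tmle_fit` object: `$estimate` (one-row tibble as in
#'   [lr_or()]), `$components` (nuisance predictions, clever covariates,
#'   `epsilon`, targeted predictions, `p1`, `p0`) and the three `sl_fit`
#'   objects.  `tidy()` returns the estimate row; `glance()` a one-row
#'   diagnostic summary.
#' @examples
#' cohort <- generate_cohort(1000, seed = 1)
#' fit <- tmle_or(cohort, library = sl_library("glm"), folds = 5, seed = 2)
#' tidy(fit)
#' @export
tmle_or <- function(frame,
                    q_covariates = c("w3", "w4"),
                    g_covariates = c("w2", "w6"),
                    d_covariates = NULL,
                    library = sl_library("tmle1"),
                    missing = c("ipw", "cc"),
                    folds = 10,
                    g_bounds = c(0.025, 0.975),
                    q_bounds = c(5e-4, 1 - 5e-4),
                    fluctuation = c("two", "one"),
                    fluctuate = TRUE,
                    seed = NULL,
                    meta = "nnls",
                    label = NULL) {
  missing <- match.arg(missing)
  fluctuation <- match.arg(fluctuation)
  stopifnot(0 < g_bounds[1], g_bounds[1] < g_bounds[2], g_bounds[2] < 1,
            0 < q_bounds[1], q_bounds[1] < q_bounds[2], q_bounds[2] < 1)
  if (!"delta" %in% names(frame)) frame$delta <- 1L
  seed <- seed %||% sample.int(.Machine$integer.max, 1)

  if (missing == "cc") frame <- complete_cases(frame)
  obs <- frame$delta == 1L
  if (!any(obs)) abort("No rows with an observed outcome.")
  n <- nrow(frame)

  # (1) initial nuisance fits
  qfit <- sl_fit(frame[obs, , drop = FALSE], "y", c("z", q_covariates),
                 library = library, folds = folds,
                 seed = derive_seed(seed, 51L), meta = meta)
  newz <- function(zv) { nd <- frame; nd$z <- zv; nd }
  q1 <- bound_prob(predict(qfit, newz(1L)), q_bounds)
  q0 <- bound_prob(predict(qfit, newz(0L)), q_bounds)

  gfit <- sl_fit(frame, "z", g_covariates, library = library, folds = folds,
                 seed = derive_seed(seed, 52L), meta = meta)
  g1 <- bound_prob(predict(gfit, frame), g_bounds)

  dfit <- NULL
  if (missing == "ipw" && any(!obs)) {
    d_covariates <- d_covariates %||% q_covariates
    dfit <- sl_fit(frame, "delta", c("z", d_covariates), library = library,
                   folds = folds, seed = derive_seed(seed, 53L), meta = meta)
    d1w <- bound_prob(predict(dfit, newz(1L)), g_bounds)
    d0w <- bound_prob(predict(dfit, newz(0L)), g_bounds)
  } else {
    d1w <- rep(1, n)
    d0w <- rep(1, n)
  }
  dz <- ifelse(frame$z == 1L, d1w, d0w)

  # (3) targeting
  z <- frame$z
  h1 <- z / (g1 * dz)          # zero for controls
  h0 <- (1 - z) / ((1 - g1) * dz)
  q_obs <- ifelse(z == 1L, q1, q0)
  lq <- qlogis(q_obs)
  if (fluctuate) {
    fd <- data.frame(y = frame$y, h0 = h0, h1 = h1, lq = lq)[obs, ]
    eps <- tryCatch({
      if (fluctuation == "two") {
        ff <- suppressWarnings(glm(
          y ~ -1 + h0 + h1 + offset(lq), family = binomial(), data = fd,
          control = list(epsilon = 1e-14, maxit = 200)))
        if (!ff$converged) abort("Fluctuation did not converge.")
        coef(ff)[c("h0", "h1")]
      } else {
        fd$hs <- fd$h1 - fd$h0
        ff <- suppressWarnings(glm(
          y ~ -1 + hs + offset(lq), family = binomial(), data = fd,
          control = list(epsilon = 1e-14, maxit = 200)))
        if (!ff$converged) abort("Fluctuation did not converge.")
        e <- coef(ff)[["hs"]]
        c(h0 = -e, h1 = e)   # shared coefficient, sign carried by H
      }
    }, error = function(e) abort(paste0("Targeting step failed: ",
                                        conditionMessage(e))))
    if (anyNA(eps)) abort("Fluctuation produced NA coefficients.")
  } else {
    eps <- c(h0 = 0, h1 = 0)
  }

  q1s <- plogis(qlogis(q1) + eps[["h1"]] / (g1 * d1w))
  q0s <- plogis(qlogis(q0) + eps[["h0"]] / ((1 - g1) * d0w))

  # (4) evaluation
  p1 <- mean(q1s)
  p0 <- mean(q0s)
  if (p0 %in% c(0, 1) || p1 %in% c(0, 1)) abort("Degenerate targeted mean.")

  components <- list(
    q1 = q1, q0 = q0, g1 = g1, d1 = d1w, d0 = d0w,
    h = h1 - h0, epsilon = eps,
    q_star1 = q1s, q_star0 = q0s, p1 = p1, p0 = p0)

  se <- eif_se(components, frame$y, z, frame$delta, p1, p0)

  lib_tag <- if (is.character(library) && length(library) == 1 &&
                 library %in% c("glm_main")) "GLM"
             else if (identical(sort(unname(library)), sort(sl_library("tmle1")))) "TMLE1"
             else if (identical(sort(unname(library)), sort(sl_library("tmle2")))) "TMLE2"
             else "SL"
  label <- label %||% sprintf("%s (%s)",
                              if (lib_tag == "GLM") "TMLE-GLM" else lib_tag,
                              toupper(missing))

  structure(
    list(
      estimate = estimate_row(label, log(odds(p1) / odds(p0)), se$se_log_or, n),
      components = components,
      ic = se$ic,
      q_fit = qfit, g_fit = gfit, d_fit = dfit,
      options = list(missing = missing, folds = folds,
                     g_bounds = g_bounds, q_bounds = q_bounds,
                     fluctuation = fluctuation, seed = seed,
                     q_covariates = q_covariates,
                     g_covariates = g_covariates,
                     d_covariates = d_covariates)),
    class = "tmle_fit")
}

#' Efficient-influence-function standard error of the log odds ratio
#'
#' Per-subject influence-function contributions for the two counterfactual
#' means,
#' `IC_a = I(Z = a) / [g_a * P(Delta = 1 | Z = a, W)] * Delta * (Y - Q*(a, W))
#'  + Q*(a, W) - p_a`,
#' combined by the delta method on the log odds-ratio scale:
#' `IC_logOR = IC_1 / [p1 (1 - p1)] - IC_0 / [p0 (1 - p0)]`, giving
#' `SE = sd(IC_logOR) / sqrt(n)`.  After targeting, the empirical mean of
#' each influence-function column is numerically zero (the fluctuation
#' solves the corresponding score equations).
#'
#' @param components Component list of a [tmle_or()] fit (`q_star1`,
#'   `q_star0`, `g1`, `d1`, `d0`, `p1`, `p0`).
#' @param y,z,delta Outcome, treatment, observation flag.
#' @param p1,p0 Targeted counterfactual means.
#' @return List with `se_log_or` and the per-subject `ic` tibble
#'   (`ic1`, `ic0`, `ic_log_or`).
#' @export
eif_se <- function(components, y, z, delta, p1 = components$p1,
                   p0 = components$p0) {
  n <- length(y)
  if (n < 2) abort("Need at least 2 subjects for a standard error.")
  cm <- components
  r1 <- ifelse(delta == 1L & z == 1L,
               (y - cm$q_star1) / (cm$g1 * cm$d1), 0)
  r0 <- ifelse(delta == 1L & z == 0L,
               (y - cm$q_star0) / ((1 - cm$g1) * cm$d0), 0)
  ic1 <- r1 + cm$q_star1 - p1
  ic0 <- r0 + cm$q_star0 - p0
  ic_log_or <- ic1 / (p1 * (1 - p1)) - ic0 / (p0 * (1 - p0))
  list(se_log_or = sd(ic_log_or) / sqrt(n),
       ic = tibble(ic1 = ic1, ic0 = ic0, ic_log_or = ic_log_or))
}

#' @describeIn tmle_or Estimate row of a fitted TMLE.
#' @param x,object A `tmle_fit`.
#' @param ... Unused.
#' @export
tidy.tmle_fit <- function(x, ...) x$estimate

#' @describeIn tmle_or One-row diagnostics: fluctuation coefficients,
#'   counterfactual means, bound-hit counts.
#' @export
glance.tmle_fit <- function(x, ...) {
  cm <- x$components
  gb <- x$options$g_bounds
  tibble(
    p1 = cm$p1, p0 = cm$p0,
    epsilon0 = cm$epsilon[["h0"]], epsilon1 = cm$epsilon[["h1"]],
    n = x$estimate$n_used,
    g_bound_hits = sum(cm$g1 %in% gb),
    missing_mode = x$options$missing)
}

#' @export
print.tmle_fit <- function(x, ...) {
  print(x$estimate)
  invisible(x)
}
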