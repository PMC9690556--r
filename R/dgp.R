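# Structural cohort simulator: six baseline covariates, a binary treatment
# and a binary outcome, all generated from an explicit DAG with logistic
# link functions, plus both potential outcomes for the truth oracle.

#' Coefficients of the cohort-generating process
#'
#' Returns the full coefficient set of the structural data-generating
#' process.  The default values emulate a type-2-diabetes cohort:
#' `w1` sex (Bernoulli 0.6), `w2` age in years (Gaussian 60, 8), `w3` BMI in
#' kg/m2 (Gaussian 35, 6), `w4` LDL cholesterol in mg/dL (Gaussian, mean 90
#' if `w1 = 1` else 97, sd 30), `w5` insulin use and `w6` macroangiopathy
#' (Bernoulli with logistic links on age resp. BMI and sex), treatment
#' `z ~ Bernoulli(plogis(-2 + 0.05 w3 - 0.20 w5 + 0.10 w6))` and outcome
#' `y ~ Bernoulli(plogis(-3 + z - 0.05 w2 + 0.05 w4 - 0.80 w1 - 0.20 w1 w2))`.
#'
#' Every coefficient can be overridden, which is how the null-effect and
#' no-confounding configurations used in the tests are built.
#'
#' @param ... Named overrides.  Each name must be one of `w1, ..., w6, z, y`
#'   and each value a named numeric vector replacing (element-wise) the
#'   defaults for that equation.
#' @return A named list of coefficient vectors with class `dgp_config`.
#' @examples
#' dgp_config()                      # the default process
#' dgp_config(y = c(z = 0))          # null treatment effect
#' @export
dgp_config <- function(...) {
  cfg <- list(
    w1 = c(p = 0.6),
    w2 = c(mean = 60, sd = 8),
    w3 = c(mean = 35, sd = 6),
    w4 = c(mean_w1_1 = 90, mean_w1_0 = 97, sd = 30),
    w5 = c(intercept = -2, w2 = 0.05),
    w6 = c(intercept = -12, w3 = 0.5, w1 = -1),
    z  = c(intercept = -2, w3 = 0.05, w5 = -0.2, w6 = 0.1),
    y  = c(intercept = -3, z = 1, w2 = -0.05, w4 = 0.05, w1 = -0.8,
           w1_w2 = -0.2)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      abort(sprintf("Unknown equation name(s): %s", paste(bad, collapse = ", ")))
    }
    for (eq in names(dots)) {
      ov <- dots[[eq]]
      bad_coef <- setdiff(names(ov), names(cfg[[eq]]))
      if (length(bad_coef) || is.null(names(ov))) {
        abort(sprintf("Unknown coefficient(s) for `%s`: %s",
                      eq, paste(bad_coef, collapse = ", ")))
      }
      cfg[[eq]][names(ov)] <- ov
    }
  }
  structure(cfg, class = c("dgp_config", "list"))
}

#' Read or write a generating-process configuration
#'
#' The configuration serializes as YAML, one key per variable with its named
#' coefficient list, so a simulation setting can be kept under version
#' control next to the analysis that used it.
#'
#' @param path File path.
#' @param config A [dgp_config()] object.
#' @return `read_dgp_config()` returns a `dgp_config`;
#'   `write_dgp_config()` returns `path` invisibly.
#' @export
read_dgp_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(dgp_config, lapply(raw, unlist))
}

#' @rdname read_dgp_config
#' @export
write_dgp_config <- function(config, path) {
  stopifnot(inherits(config, "dgp_config"))
  yaml::write_yaml(lapply(unclass(config), as.list), path)
  invisible(path)
}

#' Simulate a cohort from the structural model
#'
#' Draws `n` subjects in the topological order of the DAG
#' (`w1, w2, w3, w4, w5, w6, z, y`).  Both potential outcomes `y0` (treatment
#' forced to 0) and `y1` (forced to 1) are generated from one shared uniform
#' exogenous draw per subject (`y_a = 1` iff `u < plogis(eta_a)`), so the
#' observed outcome satisfies consistency, `y = z * y1 + (1 - z) * y0`,
#' row by row.  The observation flag `delta` starts at 1 (fully observed);
#' the amputation functions overwrite it.
#'
#' Each variable is drawn under its own child stream of `seed`, so overriding
#' a downstream equation never perturbs upstream draws.
#'
#' @param n Number of subjects (`n = 0` gives an empty, fully-typed tibble).
#' @param seed Integer root seed.
#' @param config Coefficients from [dgp_config()].
#' @return A tibble with columns `w1..w6, z, y, delta, y0, y1`.
#'   The potential-outcome columns exist for the truth oracle and the
#'   simulation harness only; no estimator reads them.
#' @examples
#' cohort <- generate_cohort(500, seed = 1)
#' mean(cohort$y)
#' @export
generate_cohort <- function(n, seed = NULL, config = dgp_config()) {
  stopifnot(inherits(config, "dgp_config"))
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0) {
    abort("`n` must be a single non-negative number.")
  }
  n <- as.integer(n)
  if (n == 0L) {
    return(tibble(
      w1 = integer(), w2 = double(), w3 = double(), w4 = double(),
      w5 = integer(), w6 = integer(), z = integer(), y = integer(),
      delta = integer(), y0 = integer(), y1 = integer()
    ))
  }
  seed <- seed %||% sample.int(.Machine$integer.max, 1)

  draw <- function(stream, fn) {
    set.seed(derive_seed(seed, stream))
    fn()
  }
  cf <- config
  w1 <- draw(1L, function() rbinom(n, 1L, cf$w1[["p"]]))
  w2 <- draw(2L, function() rnorm(n, cf$w2[["mean"]], cf$w2[["sd"]]))
  w3 <- draw(3L, function() rnorm(n, cf$w3[["mean"]], cf$w3[["sd"]]))
  w4 <- draw(4L, function() {
    mu <- ifelse(w1 == 1L, cf$w4[["mean_w1_1"]], cf$w4[["mean_w1_0"]])
    rnorm(n, mu, cf$w4[["sd"]])
  })
  w5 <- draw(5L, function() {
    rbinom(n, 1L, inv_logit(cf$w5[["intercept"]] + cf$w5[["w2"]] * w2))
  })
  w6 <- draw(6L, function() {
    rbinom(n, 1L, inv_logit(cf$w6[["intercept"]] + cf$w6[["w3"]] * w3 +
                              cf$w6[["w1"]] * w1))
  })
  z <- draw(7L, function() {
    rbinom(n, 1L, inv_logit(cf$z[["intercept"]] + cf$z[["w3"]] * w3 +
                              cf$z[["w5"]] * w5 + cf$z[["w6"]] * w6))
  })
  u <- draw(8L, function() runif(n))
  eta <- function(zv) {
    cf$y[["intercept"]] + cf$y[["z"]] * zv + cf$y[["w2"]] * w2 +
      cf$y[["w4"]] * w4 + cf$y[["w1"]] * w1 + cf$y[["w1_w2"]] * w1 * w2
  }
  y1 <- as.integer(u < inv_logit(eta(1)))
  y0 <- as.integer(u < inv_logit(eta(0)))
  y  <- ifelse(z == 1L, y1, y0)

  tibble(
    w1 = as.integer(w1), w2 = w2, w3 = w3, w4 = w4,
    w5 = as.integer(w5), w6 = as.integer(w6),
    z = as.integer(z), y = as.integer(y), delta = 1L,
    y0 = y0, y1 = y1
  )
}

#' True marginal odds ratio by counterfactual Monte Carlo
#'
#' Evaluates the causal estimand of the generating process: the odds of the
#' everyone-treated outcome mean over the odds of the everyone-untreated
#' mean, `[p1 / (1 - p1)] / [p0 / (1 - p0)]` with `p_a = E(Y_a)`, computed
#' over `n_mc` fresh counterfactual pairs.  Under the default coefficients
#' this is about 1.66 — well below the conditional odds ratio `exp(1) = 2.72`
#' of the outcome equation, the usual non-collapsibility gap.
#'
#' Draws are processed in chunks so the 5-million-subject default fits in
#' modest memory.
#'
#' @param config Coefficients from [dgp_config()].
#' @param n_mc Monte-Carlo size (at least 1e5).
#' @param seed Integer seed.
#' @param chunk_size Subjects per chunk.
#' @return A one-row tibble with class `true_effect`: `m_or`, `p1`, `p0`,
#'   `n_mc`.
#' @examples
#' true_marginal_or(n_mc = 1e5, seed = 1)
#' @export
true_marginal_or <- function(config = dgp_config(), n_mc = 5e6, seed = NULL,
                             chunk_size = 1e6) {
  stopifnot(inherits(config, "dgp_config"))
  if (n_mc < 1e5) abort("`n_mc` must be at least 1e5 for a stable estimate.")
  seed <- seed %||% sample.int(.Machine$integer.max, 1)
  sizes <- rep(chunk_size, n_mc %/% chunk_size)
  if (n_mc %% chunk_size) sizes <- c(sizes, n_mc %% chunk_size)
  s1 <- 0; s0 <- 0
  for (i in seq_along(sizes)) {
    ch <- generate_cohort(sizes[[i]], seed = derive_seed(seed, 100L + i),
                          config = config)
    s1 <- s1 + sum(ch$y1)
    s0 <- s0 + sum(ch$y0)
  }
  p1 <- s1 / n_mc
  p0 <- s0 / n_mc
  if (p0 %in% c(0, 1) || p1 %in% c(0, 1)) {
    abort("Degenerate counterfactual outcome mean (0 or 1); odds undefined.")
  }
  structure(
    tibble(m_or = odds(p1) / odds(p0), p1 = p1, p0 = p0, n_mc = n_mc),
    class = c("true_effect", class(tibble())))
}
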