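# Outcome amputation: deliberately introducing missing values in the binary
# outcome under MNAR, MAR or MCAR mechanisms at a controlled overall rate.

#' Missingness probability for non-events given an overall target rate
#'
#' Under the MNAR mechanism the probability of a missing outcome is fixed at
#' `p1_miss` for events (`y = 1`).  The probability for non-events is then
#' determined by the overall-rate constraint
#' `p1_miss * p_y1 + p0 * (1 - p_y1) = target_rate`.  The solution is clamped
#' to `[0, 1]` with a warning when the constraint is infeasible (for example
#' a target rate below `p1_miss * p_y1`).
#'
#' @param target_rate Overall fraction of subjects with a missing outcome.
#' @param p1_miss Missingness probability among events.
#' @param p_y1 Event prevalence `P(Y = 1)`, strictly inside `(0, 1)`.
#' @return The missingness probability among non-events.
#' @examples
#' solve_p0(0.40, 0.70, 0.5) # 0.10
#' @export
solve_p0 <- function(target_rate, p1_miss, p_y1) {
  stopifnot(target_rate >= 0, target_rate < 1,
            p1_miss >= 0, p1_miss <= 1)
  if (p_y1 <= 0 || p_y1 >= 1) {
    abort("`p_y1` must be strictly inside (0, 1).")
  }
  p0 <- (target_rate - p1_miss * p_y1) / (1 - p_y1)
  if (p0 < 0 || p0 > 1) {
    warn(sprintf(
      "Overall rate %.3f infeasible with P(miss | Y=1) = %.2f and P(Y=1) = %.3f; clamping.",
      target_rate, p1_miss, p_y1))
    p0 <- min(max(p0, 0), 1)
  }
  p0
}

#' Impose missingness on the outcome
#'
#' Overwrites the observation flag `delta` of a fully observed cohort under
#' one of three mechanisms:
#'
#' * `"mnar"` — missingness depends on the outcome itself:
#'   `P(delta = 0 | y = 1) = p_miss_given_y1` (default 0.70), and the
#'   non-event probability is solved from the overall `target_rate` using the
#'   cohort's empirical event prevalence ([solve_p0()]).
#' * `"mar"` — missingness depends on an equal-weight sum score of the
#'   standardized covariates `w1..w6` and `z` (the outcome is excluded):
#'   `P(delta = 0) = plogis(score - shift)`, a right-tailed logistic rule so
#'   higher-score subjects are more likely to be missing, with `shift` solved
#'   numerically so the expected overall rate equals `target_rate`.
#'   Covariates are standardized before weighting because their raw scales
#'   differ by orders of magnitude.
#' * `"mcar"` — missingness completely at random at `target_rate`.
#'
#' The outcome column is kept intact (the simulation harness needs the truth
#' for auditing); estimators must honour `delta` and only ever read `y` where
#' `delta = 1`.  Use [mask_outcome()] to blank the hidden values, e.g. before
#' exporting a cohort.
#'
#' @param frame Cohort tibble with `y` fully observed.
#' @param mechanism `"mnar"`, `"mar"` or `"mcar"`.
#' @param target_rate Overall fraction with `delta = 0`, in `[0, 1)`.
#' @param p_miss_given_y1 MNAR only: `P(delta = 0 | y = 1)`.
#' @param seed Integer seed.
#' @return `frame` with `delta` replaced.
#' @examples
#' cohort <- generate_cohort(2000, seed = 1)
#' amputed <- ampute_outcome(cohort, "mnar", target_rate = 0.2, seed = 2)
#' mean(amputed$delta == 0)
#' @export
ampute_outcome <- function(frame, mechanism = c("mnar", "mar", "mcar"),
                           target_rate, p_miss_given_y1 = 0.70, seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (nrow(frame) == 0) abort("Cannot ampute an empty cohort.")
  if (anyNA(frame$y)) abort("`y` must be fully observed before amputation.")
  stopifnot(target_rate >= 0, target_rate < 1)
  check_binary(frame$y, "y")
  seed <- seed %||% sample.int(.Machine$integer.max, 1)

  p_miss <- switch(
    mechanism,
    mnar = {
      p_y1 <- mean(frame$y)
      if (p_y1 <= 0 || p_y1 >= 1) {
        abort("Outcome is constant; MNAR amputation undefined.")
      }
      p0 <- solve_p0(target_rate, p_miss_given_y1, p_y1)
      ifelse(frame$y == 1, p_miss_given_y1, p0)
    },
    mar = {
      score <- mar_sum_score(frame)
      right_tail_probs(score, target_rate)
    },
    mcar = rep(target_rate, nrow(frame))
  )

  set.seed(derive_seed(seed, 31L))
  miss <- runif(nrow(frame)) < p_miss
  frame$delta <- as.integer(!miss)
  frame
}

# Equal-weight sum of standardized covariates (outcome excluded).
mar_sum_score <- function(frame) {
  vars <- intersect(c("w1", "w2", "w3", "w4", "w5", "w6", "z"), names(frame))
  m <- as.matrix(frame[vars])
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    # a constant column carries no information; drop rather than divide by 0
    m <- m[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (!ncol(m)) abort("All covariates constant; MAR sum score has zero variance.")
  score <- rowSums(scale(m))
  if (sd(score) == 0) abort("MAR sum score has zero variance.")
  as.numeric(scale(score))
}

# Right-tailed logistic missingness: P(miss) = plogis(score - shift), shift
# solved so the expected overall rate matches the target.
right_tail_probs <- function(score, target_rate) {
  if (target_rate == 0) return(rep(0, length(score)))
  f <- function(shift) mean(plogis(score - shift)) - target_rate
  shift <- uniroot(f, lower = -50, upper = 50, tol = 1e-10)$root
  plogis(score - shift)
}

#' Blank hidden outcome values
#'
#' Sets `y` to `NA` wherever `delta = 0`, producing the frame an analyst
#' would actually see.  Potential-outcome columns, if present, are dropped.
#'
#' @param frame Cohort tibble with a `delta` column.
#' @return The masked tibble.
#' @export
mask_outcome <- function(frame) {
  frame$y[frame$delta == 0L] <- NA_integer_
  frame[setdiff(names(frame), c("y0", "y1"))]
}
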