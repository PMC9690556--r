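# Internal helpers shared across modules.

#' Inverse logit
#'
#' Standard inverse-logit (expit) transform, `1 / (1 + exp(-x))`.  Thin
#' validating wrapper around [stats::plogis()]: non-finite input is an error
#' rather than a silent `NA`, since every generating equation in the cohort
#' simulator passes through it.
#'
#' @param x Numeric vector of finite values on the linear-predictor scale.
#' @return Probabilities in `(0, 1)`.
#' @examples
#' inv_logit(0)              # 0.5
#' inv_logit(-2 + 0.05 * 60) # P(insulin use) at age 60 in the simulator
#' @export
inv_logit <- function(x) {
  if (!is.numeric(x)) abort("`x` must be numeric.")
  if (length(x) && any(!is.finite(x))) {
    abort("`x` must be finite (non-finite linear predictor).")
  }
  plogis(x)
}

# Deterministic child-seed derivation: one root seed, fixed integer streams.
# Drawing variable k under stream k means adding a downstream column never
# perturbs earlier draws.  Kept below 2^31 - 1 so set.seed() always accepts it.
derive_seed <- function(seed, stream) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 69621 + as.numeric(stream) * 1013904223) %% 2147483647)
}

# Truncate probabilities to [lo, hi].
bound_prob <- function(p, bounds) {
  pmin(pmax(p, bounds[[1]]), bounds[[2]])
}

check_binary <- function(x, name) {
  ok <- x[!is.na(x)]
  if (length(ok) && !all(ok %in% c(0, 1))) {
    abort(sprintf("`%s` must be binary (0/1).", name))
  }
  invisible(x)
}

# Odds of a probability strictly inside (0, 1).
odds <- function(p) p / (1 - p)
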