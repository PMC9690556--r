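# Independent oracles used to pin expected values: a hand-rolled IRLS
# logistic solver, closed-form 2x2 odds ratios, and a literal re-statement
# of greedy caliper matching.  Deliberately written without reference to the
# package internals they check.

# Iteratively reweighted least squares for logistic regression.
irls_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    zresp <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, X * w), crossprod(X, w * zresp))
    if (max(abs(beta_new - beta)) < tol) {
      return(as.numeric(beta_new))
    }
    beta <- as.numeric(beta_new)
  }
  stop("IRLS did not converge")
}

or_2x2 <- function(a, b, c, d) (a * d) / (b * c)

# Greedy 1:1 caliper matching, written as the literal textual rule:
# treated in descending score order, nearest remaining control, keep if
# within the caliper.
greedy_match_oracle <- function(lp, z, caliper) {
  treated <- order(-lp, seq_along(lp))
  treated <- treated[z[treated] == 1]
  controls <- which(z == 0)
  used <- logical(length(controls))
  out <- NULL
  for (t in treated) {
    best <- NA; bestd <- Inf
    for (k in seq_along(controls)) {
      if (used[k]) next
      d <- abs(lp[controls[k]] - lp[t])
      if (d < bestd) { bestd <- d; best <- k }
    }
    if (!is.na(best) && bestd <= caliper + 1e-12) {
      used[best] <- TRUE
      out <- rbind(out, c(t, controls[best]))
    }
  }
  out
}

# Small deterministic logistic fixture: 12 rows, well-conditioned fit
# (max |coefficient| < 8, fitted probabilities inside (0.03, 0.97)).
logistic_fixture <- function() {
  tibble::tibble(
    y = c(1, 0, 1, 0, 0, 1, 0, 1, 0, 1, 1, 1),
    z = rep(c(0L, 1L), 6),
    w3 = c(31.9, 35.9, 30.8, 43.0, 36.6, 30.9, 37.4, 38.7, 37.9, 33.5,
           42.6, 36.9),
    w4 = c(89, 73, 106, 95, 95, 104, 103, 101, 104, 103, 96, 75),
    delta = 1L
  )
}

# Cohort whose treated and control arms carry identical covariate (hence
# propensity) values pair by pair, with outcome counts chosen freely:
# a/b = events/non-events among treated, c/d among controls.
paired_cohort <- function(a, b, c, d) {
  stopifnot(a + b == c + d)
  n <- a + b
  tibble::tibble(
    w2 = rep(seq(50, 70, length.out = n), 2),
    z = rep(c(1L, 0L), each = n),
    y = c(rep(1L, a), rep(0L, b), rep(1L, c), rep(0L, d)),
    delta = 1L
  )
}

# Absolute standardized mean difference between arms.
smd <- function(x, z) {
  m1 <- mean(x[z == 1]); m0 <- mean(x[z == 0])
  s <- sqrt((var(x[z == 1]) + var(x[z == 0])) / 2)
  if (s == 0) return(0)
  abs(m1 - m0) / s
}
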