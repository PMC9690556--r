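# Monte-Carlo harness: run the estimator battery over replicated simulated
# cohorts and summarise mean OR, bias, empirical SE and nominal coverage per
# method, in the layout of the simulation study's results table.

# canonical column order of the results table
METHOD_ORDER <- c("lr", "ps_matching", "ps_covariate", "iptw",
                  "tmle1_cc", "tmle2_cc", "tmle1_ipw", "tmle2_ipw",
                  "tmle_glm_cc", "tmle_glm_ipw")

method_label <- function(m) {
  c(lr = "LR", ps_matching = "PS matching", ps_covariate = "PS covariate",
    iptw = "IPTW", tmle1_cc = "TMLE1 (CC)", tmle2_cc = "TMLE2 (CC)",
    tmle1_ipw = "TMLE1 (IPW)", tmle2_ipw = "TMLE2 (IPW)",
    tmle_glm_cc = "TMLE-GLM (CC)", tmle_glm_ipw = "TMLE-GLM (IPW)")[[m]]
}

method_fun <- function(m, folds, ps_outcome_covariates = c("w3", "w4")) {
  oc <- ps_outcome_covariates
  tm <- function(lib, mode) {
    function(frame, seed) {
      tidy(tmle_or(frame, library = sl_library(lib), missing = mode,
                   folds = folds, seed = seed, label = method_label(m)))
    }
  }
  switch(m,
    lr           = function(frame, seed) lr_or(frame),
    ps_matching  = function(frame, seed)
      ps_matching_or(frame, outcome_covariates = oc),
    ps_covariate = function(frame, seed)
      ps_covariate_or(frame, outcome_covariates = oc),
    iptw         = function(frame, seed)
      iptw_or(frame, outcome_covariates = oc),
    tmle1_cc     = tm("tmle1", "cc"),
    tmle1_ipw    = tm("tmle1", "ipw"),
    tmle2_cc     = tm("tmle2", "cc"),
    tmle2_ipw    = tm("tmle2", "ipw"),
    tmle_glm_cc  = tm("glm", "cc"),
    tmle_glm_ipw = tm("glm", "ipw"),
    abort(sprintf("Unknown method `%s`.", m))
  )
}

#' Define a Monte-Carlo scenario
#'
#' A scenario bundles cohort size, missingness mechanism and rate, number of
#' replicates, the methods to compare and a root seed.  [scenario_preset()]
#' returns the four benchmark scenarios of the simulation study (20% or 40%
#' MNAR outcome missingness crossed with n = 1000 or 5000; the study default
#' is 1000 replicates).
#'
#' @param n Cohort size per replicate.
#' @param mechanism Missingness mechanism ([ampute_outcome()]).
#' @param target_rate Overall missingness rate.
#' @param reps Number of Monte-Carlo replicates.
#' @param methods Character vector of method keys among `lr, ps_matching,
#'   ps_covariate, iptw, tmle1_cc, tmle2_cc, tmle1_ipw, tmle2_ipw,
#'   tmle_glm_cc, tmle_glm_ipw`.
#' @param seed Root seed; every replicate derives its own child seed.
#' @return A `scenario` list.
#' @export
scenario <- function(n, mechanism = "mnar", target_rate = 0.2, reps = 1000,
                     methods = c("lr", "ps_matching", "ps_covariate", "iptw",
                                 "tmle1_cc", "tmle1_ipw"),
                     seed = 1L) {
  stopifnot(reps >= 1, n >= 1)
  bad <- setdiff(methods, METHOD_ORDER)
  if (length(bad)) abort(sprintf("Unknown method(s): %s",
                                 paste(bad, collapse = ", ")))
  structure(list(n = as.integer(n), mechanism = mechanism,
                 target_rate = target_rate, reps = as.integer(reps),
                 methods = methods, seed = as.integer(seed)),
            class = "scenario")
}

#' @rdname scenario
#' @param id Preset number 1-4: (1) 20% MNAR, n = 1000; (2) 40% MNAR,
#'   n = 1000; (3) 20% MNAR, n = 5000; (4) 40% MNAR, n = 5000.
#' @param ... Overrides passed to [scenario()].
#' @export
scenario_preset <- function(id, ...) {
  stopifnot(id %in% 1:4)
  base <- list(
    list(n = 1000L, target_rate = 0.2),
    list(n = 1000L, target_rate = 0.4),
    list(n = 5000L, target_rate = 0.2),
    list(n = 5000L, target_rate = 0.4))[[id]]
  args <- utils::modifyList(c(base, list(mechanism = "mnar")), list(...))
  do.call(scenario, args)
}

#' Run a Monte-Carlo scenario
#'
#' For each replicate: generate a cohort from the structural model, impose
#' outcome missingness, run every requested estimator, and record its point
#' estimate and confidence interval.  Per-method summaries report the mean
#' OR, bias (`mean OR - true OR`), the empirical SE (standard deviation of
#' the estimates across replicates), the nominal 95% coverage (percentage of
#' replicates whose interval contains the true OR) and the mean model-based
#' SE of the log OR.  Replicates where a method fails are excluded from that
#' method's summary; more than 5% failures for any method is an error, since
#' it indicates a broken configuration rather than occasional degeneracy.
#'
#' Every replicate derives a child seed from the scenario seed, so a run is
#' reproducible bit for bit, including the stochastic learners.
#'
#' @param sc A [scenario()].
#' @param true_or True marginal OR; either a number, a `true_effect`, or
#'   `NULL` to compute it by counterfactual Monte Carlo (1e6 draws) from
#'   `config`.
#' @param folds Cross-validation folds used by the TMLE super learners.
#' @param config Generating-process coefficients.
#' @param ps_outcome_covariates Covariates retained in the outcome stage of
#'   the propensity-score methods; defaults to the study's misspecified
#'   outcome model (`w3`, `w4`).  Set `NULL` for the bare `y ~ z` outcome
#'   stage.
#' @param verbose Print per-replicate progress.
#' @return A `scenario_summary` object: `$summary` (per-method tibble),
#'   `$replicates` (one row per replicate x method), `$failures`,
#'   `$true_or`, `$scenario`.  `tidy()` returns the summary tibble.
#' @examples
#' sc <- scenario(400, target_rate = 0.2, reps = 3, methods = "lr", seed = 7)
#' run_scenario(sc, true_or = 1.66)
#' @export
run_scenario <- function(sc, true_or = NULL, folds = 5,
                         config = dgp_config(),
                         ps_outcome_covariates = c("w3", "w4"),
                         verbose = FALSE) {
  stopifnot(inherits(sc, "scenario"))
  if (is.null(true_or)) {
    true_or <- true_marginal_or(config, n_mc = 1e6,
                                seed = derive_seed(sc$seed, 9L))$m_or
  } else if (inherits(true_or, "true_effect")) {
    true_or <- true_or$m_or
  }

  fns <- lapply(sc$methods, method_fun, folds = folds,
                ps_outcome_covariates = ps_outcome_covariates)
  names(fns) <- sc$methods

  rows <- vector("list", sc$reps)
  fails <- list()
  for (r in seq_len(sc$reps)) {
    seed_r <- derive_seed(sc$seed, 10000L + r)
    cohort <- generate_cohort(sc$n, seed = seed_r, config = config)
    am <- ampute_outcome(cohort, sc$mechanism, sc$target_rate,
                         seed = derive_seed(seed_r, 1L))
    est <- lapply(sc$methods, function(m) {
      out <- tryCatch(fns[[m]](am, derive_seed(seed_r, 2L)),
                      error = function(e) e)
      if (inherits(out, "error")) {
        fails[[length(fails) + 1L]] <<- tibble(
          replicate = r, method = m, message = conditionMessage(out))
        return(NULL)
      }
      out$method <- m
      out
    })
    rows[[r]] <- bind_rows(est)
    rows[[r]]$replicate <- if (nrow(rows[[r]])) r else integer(0)
    if (verbose && r %% 10 == 0) {
      inform(sprintf("replicate %d / %d", r, sc$reps))
    }
  }
  reps_tbl <- bind_rows(rows)
  fail_tbl <- bind_rows(fails)
  if (nrow(fail_tbl)) {
    frac <- table(factor(fail_tbl$method, sc$methods)) / sc$reps
    if (any(frac > 0.05)) {
      abort(sprintf("Method(s) failed in more than 5%% of replicates: %s",
                    paste(names(frac)[frac > 0.05], collapse = ", ")))
    }
  }

  summary_tbl <- reps_tbl |>
    mutate(method = factor(.data$method, levels = sc$methods)) |>
    group_by(method = .data$method) |>
    summarise(
      reps_completed = dplyr::n(),
      mean_or = mean(.data$or),
      bias = mean(.data$or) - true_or,
      se_emp = if (dplyr::n() > 1) sd(.data$or) else NA_real_,
      coverage_pct = 100 * mean(.data$ci_low <= true_or &
                                  true_or <= .data$ci_high),
      mean_se_log = mean(.data$se_log_or),
      .groups = "drop") |>
    mutate(method = as.character(.data$method))

  structure(
    list(summary = summary_tbl, replicates = reps_tbl, failures = fail_tbl,
         true_or = true_or, scenario = sc),
    class = "scenario_summary")
}

#' @describeIn run_scenario Per-method summary tibble.
#' @param x A `scenario_summary`.
#' @param ... Unused.
#' @export
tidy.scenario_summary <- function(x, ...) x$summary

#' @describeIn run_scenario One-row scenario description.
#' @export
glance.scenario_summary <- function(x, ...) {
  sc <- x$scenario
  tibble(n = sc$n, mechanism = sc$mechanism, target_rate = sc$target_rate,
         reps = sc$reps, true_or = x$true_or,
         n_failures = nrow(x$failures))
}

#' @export
print.scenario_summary <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("Scenario: %.0f%% %s on Y, n = %d, %d replicates (true OR %.3f)\n",
              100 * sc$target_rate, toupper(sc$mechanism), sc$n, sc$reps,
              x$true_or))
  print(x$summary)
  invisible(x)
}

#' @describeIn run_scenario Dot-and-interval plot of the per-method mean OR
#'   (interval: +/- empirical SE) against the true marginal OR.
#' @param object A `scenario_summary`.
#' @export
autoplot.scenario_summary <- function(object, ...) {
  d <- object$summary |>
    mutate(label = vapply(.data$method, method_label, ""))
  ggplot(d, aes(x = .data$label, y = .data$mean_or)) +
    geom_hline(yintercept = object$true_or, linetype = 2, colour = "grey40") +
    geom_pointrange(aes(ymin = .data$mean_or - .data$se_emp,
                        ymax = .data$mean_or + .data$se_emp)) +
    coord_flip() +
    labs(x = NULL, y = "mean estimated OR (+/- empirical SE)",
         title = sprintf("%.0f%% %s, n = %d",
                         100 * object$scenario$target_rate,
                         toupper(object$scenario$mechanism),
                         object$scenario$n)) +
    theme_bw()
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' Combines `m` repeated estimates (for odds ratios, work on the log scale)
#' with total variance `W + (1 + 1/m) B`, where `W` is the mean
#' within-imputation variance and `B` the between-imputation variance, and
#' the Barnard-Rubin small-sample degrees of freedom when a complete-data
#' `df_com` is supplied.
#'
#' @param estimates Numeric vector of point estimates.
#' @param variances Numeric vector of their squared standard errors.
#' @param df_com Complete-data degrees of freedom (default `Inf`, giving the
#'   classical large-sample df).
#' @return One-row tibble: `estimate, se, df, m, within, between`.
#' @examples
#' rubins_pool(c(0.2, 0.4), c(0.01, 0.01))
#' @export
rubins_pool <- function(estimates, variances, df_com = Inf) {
  if (length(estimates) != length(variances)) {
    abort("`estimates` and `variances` must have the same length.")
  }
  m <- length(estimates)
  if (m == 0) abort("Nothing to pool.")
  if (m == 1) {
    warn("Only one estimate supplied; returning it unpooled.")
    return(tibble(estimate = estimates, se = sqrt(variances), df = Inf,
                  m = 1L, within = variances, between = 0))
  }
  qbar <- mean(estimates)
  wbar <- mean(variances)
  b <- var(estimates)
  total <- wbar + (1 + 1 / m) * b
  if (b == 0) {
    df <- Inf
  } else {
    r <- (1 + 1 / m) * b / wbar
    df_old <- (m - 1) * (1 + 1 / r)^2
    if (is.finite(df_com)) {
      lambda <- (1 + 1 / m) * b / total
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
      df <- 1 / (1 / df_old + 1 / df_obs)
    } else {
      df <- df_old
    }
  }
  tibble(estimate = qbar, se = sqrt(total), df = df, m = m,
         within = wbar, between = b)
}

# ---- results-table rendering ----------------------------------------------

fmt_cell <- function(v) {
  ifelse(!is.finite(v), "NA",
         ifelse(abs(v) < 0.01, sprintf("%.3f", v), sprintf("%.2f", v)))
}

#' Render and parse the results table
#'
#' `report_table()` lays out one block per scenario with rows `OR`, `Bias`,
#' `SE` and `95% NCI` and one column per method, tab-delimited, values
#' rounded to 2 decimals (3 when below 0.01, so near-zero biases stay
#' visible).  `parse_report_table()` reads the rendered text back into a
#' long tibble.
#'
#' @param summaries A `scenario_summary` or list of them.
#' @return `report_table()`: character vector of lines;
#'   `parse_report_table()`: tibble with `scenario, statistic, method,
#'   value`.
#' @export
report_table <- function(summaries) {
  if (inherits(summaries, "scenario_summary")) summaries <- list(summaries)
  stopifnot(length(summaries) >= 1)
  out <- character(0)
  for (s in summaries) {
    sc <- s$scenario
    head <- sprintf("SCENARIO: %.0f%% %s on Y, n = %d",
                    100 * sc$target_rate, toupper(sc$mechanism), sc$n)
    labels <- vapply(s$summary$method, method_label, "")
    rows <- rbind(
      `OR` = fmt_cell(s$summary$mean_or),
      `Bias` = fmt_cell(s$summary$bias),
      `SE` = fmt_cell(s$summary$se_emp),
      `95% NCI` = fmt_cell(s$summary$coverage_pct))
    out <- c(out, head, paste(c("", labels), collapse = "\t"),
             vapply(rownames(rows), function(rn) {
               paste(c(rn, rows[rn, ]), collapse = "\t")
             }, ""))
  }
  out
}

#' @rdname report_table
#' @param lines Character vector produced by `report_table()`.
#' @export
parse_report_table <- function(lines) {
  res <- list()
  scen <- NA_character_
  methods <- character(0)
  for (ln in lines) {
    if (startsWith(ln, "SCENARIO:")) {
      scen <- sub("^SCENARIO: ", "", ln)
    } else {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (parts[[1]] == "") {
        methods <- parts[-1]
      } else {
        res[[length(res) + 1L]] <- tibble(
          scenario = scen, statistic = parts[[1]], method = methods,
          value = suppressWarnings(as.numeric(parts[-1])))
      }
    }
  }
  bind_rows(res)
}
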