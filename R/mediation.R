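#' Causal mediation analysis for a binary outcome
#'
#' Estimates the average causal mediation effect (ACME), average direct
#' effect (ADE), total effect, and proportion mediated on the
#' risk-difference (probability) scale for an exposure -> mediator ->
#' binary-outcome path. Two models are fit: a linear regression of the
#' mediator on the exposure (plus covariates), and a logistic regression
#' of the outcome on exposure and mediator (plus covariates).
#'
#' Uncertainty comes from the quasi-Bayesian potential-outcomes algorithm:
#' model parameters are drawn `n_draws` times from their asymptotic normal
#' distribution; for each draw, counterfactual mediator values are
#' simulated at the two exposure contrast levels (mean +/- 1 SD for a
#' continuous exposure) with shared residual draws, the four
#' potential-outcome probabilities are averaged, and effects are formed so
#' that ACME + ADE equals the total effect exactly within every draw.
#' Point estimates are means over draws; 95% intervals are percentile
#' intervals.
#'
#' @param exposure numeric vector.
#' @param mediator numeric vector.
#' @param outcome 0/1 vector (both classes required).
#' @param covariates optional data.frame of adjustment covariates entered
#'   into both models; averaged over the observed sample when simulating.
#' @param n_draws parameter draws (default 1000).
#' @param sims_per_draw mediator residual simulations per draw (default
#'   200).
#' @param seed RNG seed.
#' @param contrast length-2 numeric (control, treated) exposure levels;
#'   default `mean(exposure) -/+ sd(exposure)`.
#' @return `ow_mediation`: `estimates` data.frame (effect, estimate,
#'   ci_lower, ci_upper, mc_se, significant), `proportion_mediated` (NA
#'   unless the total-effect CI excludes zero), `contrast`, `n_used`,
#'   `n_dropped`, `n_draws`.
#' @export
mediate <- function(exposure, mediator, outcome, covariates = NULL,
                    n_draws = 1000, sims_per_draw = 200, seed = 1L,
                    contrast = NULL) {
  df <- data.frame(.x = exposure, .m = mediator, .y = outcome)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  n0 <- nrow(df)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n_dropped <- n0 - nrow(df)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) with missing values dropped")
  }
  if (nrow(df) < 10) stop("fewer than 10 complete rows")
  if (length(unique(df$.y)) < 2 || !all(df$.y %in% 0:1)) {
    stop("outcome must be 0/1 with both classes present")
  }
  cov_names <- setdiff(names(df), c(".x", ".m", ".y"))
  m_form <- stats::reformulate(c(".x", cov_names), response = ".m")
  y_form <- stats::reformulate(c(".x", ".m", cov_names), response = ".y")
  m_fit <- stats::lm(m_form, data = df)
  y_fit <- suppressWarnings(
    stats::glm(y_form, data = df, family = stats::binomial())
  )
  fv <- stats::fitted(y_fit)
  if (any(fv < 1e-10) || any(fv > 1 - 1e-10) ||
      max(abs(stats::coef(y_fit))) > 25) {
    stop(
      "separation detected in the logistic outcome model; ",
      "consider a penalized fit or rescaling the mediator"
    )
  }
  if (is.null(contrast)) {
    contrast <- c(
      mean(df$.x) - stats::sd(df$.x),
      mean(df$.x) + stats::sd(df$.x)
    )
  }
  x0 <- contrast[1]
  x1 <- contrast[2]
  sigma_m <- stats::summary.lm(m_fit)$sigma

  set.seed(seed)
  th_m <- MASS::mvrnorm(n_draws, stats::coef(m_fit), stats::vcov(m_fit))
  th_y <- MASS::mvrnorm(n_draws, stats::coef(y_fit), stats::vcov(y_fit))
  # covariates enter through their sample-average linear contribution
  cov_mean_m <- 0
  cov_mean_y <- 0
  if (length(cov_names) > 0) {
    cm <- colMeans(df[, cov_names, drop = FALSE])
    cov_mean_m <- as.numeric(th_m[, cov_names, drop = FALSE] %*% cm)
    cov_mean_y <- as.numeric(th_y[, cov_names, drop = FALSE] %*% cm)
  }
  e <- matrix(
    stats::rnorm(n_draws * sims_per_draw, sd = sigma_m),
    n_draws, sims_per_draw
  )
  m_at <- function(x) {
    th_m[, "(Intercept)"] + th_m[, ".x"] * x + cov_mean_m + e
  }
  m1 <- m_at(x1)
  m0 <- m_at(x0)
  p_at <- function(x, m) {
    stats::plogis(
      th_y[, "(Intercept)"] + th_y[, ".x"] * x + cov_mean_y +
        th_y[, ".m"] * m
    )
  }
  delta1 <- rowMeans(p_at(x1, m1) - p_at(x1, m0))
  delta0 <- rowMeans(p_at(x0, m1) - p_at(x0, m0))
  zeta1 <- rowMeans(p_at(x1, m1) - p_at(x0, m1))
  zeta0 <- rowMeans(p_at(x1, m0) - p_at(x0, m0))
  acme_d <- (delta1 + delta0) / 2
  ade_d <- (zeta1 + zeta0) / 2
  total_d <- acme_d + ade_d # exact per-draw identity

  summ <- function(d) {
    ci <- unname(stats::quantile(d, c(0.025, 0.975)))
    c(
      estimate = mean(d), ci_lower = ci[1], ci_upper = ci[2],
      mc_se = stats::sd(d) / sqrt(length(d))
    )
  }
  est <- rbind(
    acme = summ(acme_d), ade = summ(ade_d), total = summ(total_d)
  )
  est <- data.frame(effect = rownames(est), est, row.names = NULL)
  est$significant <- est$ci_lower > 0 | est$ci_upper < 0
  total_sig <- est$significant[est$effect == "total"]
  prop <- if (isTRUE(total_sig)) {
    est$estimate[est$effect == "acme"] /
      est$estimate[est$effect == "total"]
  } else {
    NA_real_
  }
  structure(
    list(
      estimates = est,
      proportion_mediated = prop,
      contrast = c(control = x0, treated = x1),
      n_used = nrow(df), n_dropped = n_dropped,
      n_draws = n_draws, sims_per_draw = sims_per_draw
    ),
    class = "ow_mediation"
  )
}

#' @export
print.ow_mediation <- function(x, ...) {
  cat(
    "Mediation (risk-difference scale), exposure contrast",
    sprintf("%.3f -> %.3f", x$contrast[1], x$contrast[2]), "\n"
  )
  df <- x$estimates
  df[, 2:5] <- round(df[, 2:5], 5)
  print(df, row.names = FALSE)
  if (!is.na(x$proportion_mediated)) {
    cat(sprintf(
      "Proportion mediated: %.1f%%\n", 100 * x$proportion_mediated
    ))
  } else {
    cat("Proportion mediated: not reported (total effect CI covers 0)\n")
  }
  invisible(x)
}

#' Screen exposure/mediator pairs for mediation of a binary stage outcome
#'
#' Batch interface: every (clinical exposure, metabolite mediator) pair is
#' tested for mediation of the binary outcome "osteopenia vs control"
#' (configurable stage pair), producing a long-format table.
#'
#' @param x staged `ow_cohort`.
#' @param exposures metadata column names used as exposures.
#' @param mediators metabolite ids used as mediators (e.g. the selected
#'   biomarker panel).
#' @param outcome_stages stage pair; the second level codes outcome = 1.
#' @param ... passed to [mediate()].
#' @return data.frame: exposure, mediator, acme, acme_lower, acme_upper,
#'   total, total_lower, total_upper, proportion_mediated, significant
#'   (both total and ACME CIs exclude zero).
#' @export
mediate_screen <- function(x, exposures, mediators,
                           outcome_stages = c("control", "osteopenia"),
                           ...) {
  stopifnot(inherits(x, "ow_cohort"))
  st <- cohort_stage(x)
  keep <- st %in% outcome_stages
  md <- x$metadata[keep, , drop = FALSE]
  ab <- x$abundance[keep, , drop = FALSE]
  y <- as.integer(st[keep] == outcome_stages[2])
  grid <- expand.grid(
    exposure = exposures, mediator = mediators,
    stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    res <- mediate(
      exposure = as.numeric(md[[grid$exposure[i]]]),
      mediator = ab[, grid$mediator[i]],
      outcome = y, ...
    )
    est <- res$estimates
    a <- est[est$effect == "acme", ]
    t <- est[est$effect == "total", ]
    data.frame(
      exposure = grid$exposure[i], mediator = grid$mediator[i],
      acme = a$estimate, acme_lower = a$ci_lower, acme_upper = a$ci_upper,
      total = t$estimate, total_lower = t$ci_lower,
      total_upper = t$ci_upper,
      proportion_mediated = res$proportion_mediated,
      significant = a$significant && t$significant,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
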