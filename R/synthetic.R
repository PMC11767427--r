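#' Simulation configuration for a three-stage synthetic cohort
#'
#' Defines a cohort drawn from stage-specific multivariate log-normal
#' distributions with a planted dynamic-network-biomarker (DNB) block: a
#' "domain" set whose intra-block correlation and variance surge at the
#' middle (osteopenia-analog) stage while its correlation to the background
#' drops, mimicking the tipping-point premise that the critical state -- not
#' the end-stage disease -- is maximally coupled and variable. A subset of
#' background metabolites additionally carries a monotone mean trend across
#' stages.
#'
#' Per-stage parameter vectors are ordered (control, osteopenia,
#' osteoporosis). Background metabolites share a weak constant correlation
#' of 0.1. Each stage's full correlation matrix must be positive definite;
#' this is checked at build time and violations are an error naming the
#' offending stage.
#'
#' @param n_per_stage samples per stage (default 50).
#' @param n_metabolites total metabolites (default 60).
#' @param domain_size size of the planted DNB block (default 10).
#' @param rho_in per-stage intra-domain correlation.
#' @param rho_out per-stage domain-to-background correlation.
#' @param sd_scale per-stage multiplier of the domain log-scale SD.
#' @param n_trend number of background metabolites with a monotone mean
#'   shift across stages (default 8).
#' @param trend_step mean shift per stage step, in units of the log-scale SD.
#' @param mediation list with elements `alpha` (exposure to mediator slope),
#'   `beta` (mediator to outcome log-odds) and `gamma` (direct exposure to
#'   outcome log-odds), used by [generate_mediation_data()].
#' @param missing_fraction fraction of abundance cells blanked missing at
#'   random (default 0.05; must be below 0.5).
#' @param missing_mode `"mar"` for uniform missing-at-random, or
#'   `"left_censor"` to blank the lowest cells per metabolite (a
#'   detection-limit analog).
#' @param gender single gender label stamped on the whole stratum.
#' @param seed default seed used by the generators.
#' @return A classed list of validated parameters (`ow_sim_config`).
#' @export
sim_config <- function(n_per_stage = 50,
                       n_metabolites = 60,
                       domain_size = 10,
                       rho_in = c(0.2, 0.7, 0.35),
                       rho_out = c(0.15, 0.05, 0.10),
                       sd_scale = c(1.0, 2.0, 1.3),
                       n_trend = 8,
                       trend_step = 0.5,
                       mediation = list(alpha = 0.5, beta = 0.8, gamma = 0.3),
                       missing_fraction = 0.05,
                       missing_mode = c("mar", "left_censor"),
                       gender = "female",
                       seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  stopifnot(
    n_per_stage >= 2, n_metabolites >= 4,
    domain_size >= 2, domain_size < n_metabolites,
    length(rho_in) == 3, length(rho_out) == 3, length(sd_scale) == 3,
    all(sd_scale > 0), n_trend >= 0,
    n_trend <= n_metabolites - domain_size,
    missing_fraction >= 0, missing_fraction < 0.5,
    all(c("alpha", "beta", "gamma") %in% names(mediation))
  )
  cfg <- structure(
    list(
      n_per_stage = as.integer(n_per_stage),
      n_metabolites = as.integer(n_metabolites),
      domain_size = as.integer(domain_size),
      rho_in = rho_in, rho_out = rho_out, sd_scale = sd_scale,
      rho_background = 0.1,
      n_trend = as.integer(n_trend), trend_step = trend_step,
      mediation = mediation,
      missing_fraction = missing_fraction,
      missing_mode = missing_mode,
      gender = gender,
      seed = as.integer(seed),
      log_mu = 3, log_sd = 0.25
    ),
    class = "ow_sim_config"
  )
  for (s in 1:3) stage_correlation(cfg, s) # PD check, errors if violated
  cfg
}

# Stage correlation matrix; errors on non-positive-definite parameter sets.
stage_correlation <- function(cfg, stage_index) {
  p <- cfg$n_metabolites
  d <- cfg$domain_size
  R <- matrix(cfg$rho_background, p, p)
  R[1:d, 1:d] <- cfg$rho_in[stage_index]
  R[1:d, (d + 1):p] <- cfg$rho_out[stage_index]
  R[(d + 1):p, 1:d] <- cfg$rho_out[stage_index]
  diag(R) <- 1
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10) {
    stop(
      "stage ", stage_index, " correlation matrix is not positive definite ",
      "(rho_in=", cfg$rho_in[stage_index],
      ", rho_out=", cfg$rho_out[stage_index],
      ", background=", cfg$rho_background, ")"
    )
  }
  R
}

#' Generate a synthetic three-stage cohort with planted ground truth
#'
#' Samples are drawn per stage from a multivariate normal on the log scale
#' (block correlation per [sim_config()]; domain log-SDs multiplied by the
#' stage's `sd_scale`; trend metabolites shifted by
#' `stage_index * trend_step` log-SDs) and exponentiated, so abundances are
#' positive and approximately log-normal. Missing cells are then blanked
#' according to the configured mechanism. Output is bit-identical for a
#' fixed config and seed.
#'
#' @param config an [sim_config()].
#' @param seed overrides `config$seed` when given.
#' @return list with `cohort` (an [cohort()] with stage labels, gender, and
#'   clinical covariates including three noise bone-turnover markers) and
#'   `truth` (list: `domain_members`, `trend_members`, `trend_direction`,
#'   per-stage generative parameters, and a `null_regime` flag set when no
#'   DNB is planted).
#' @export
generate_cohort <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "ow_sim_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  p <- config$n_metabolites
  d <- config$domain_size
  n <- config$n_per_stage
  mets <- sprintf("M%03d", seq_len(p))
  domain <- mets[1:d]
  trend <- if (config$n_trend > 0) mets[d + seq_len(config$n_trend)] else character(0)

  blocks <- vector("list", 3)
  for (s in 1:3) {
    R <- stage_correlation(config, s)
    sds <- rep(config$log_sd, p)
    sds[1:d] <- sds[1:d] * config$sd_scale[s]
    mu <- rep(config$log_mu, p)
    if (length(trend) > 0) {
      mu[d + seq_len(config$n_trend)] <-
        mu[d + seq_len(config$n_trend)] +
        (s - 1) * config$trend_step * config$log_sd
    }
    Sigma <- R * tcrossprod(sds)
    blocks[[s]] <- MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
  }
  logm <- do.call(rbind, blocks)
  ab <- exp(logm)
  ids <- sprintf("S%04d", seq_len(3 * n))
  dimnames(ab) <- list(ids, mets)
  stage <- rep(stage_levels(), each = n)

  if (config$missing_fraction > 0) {
    n_miss_col <- round(config$missing_fraction * nrow(ab))
    for (j in seq_len(p)) {
      if (n_miss_col == 0) break
      idx <- if (config$missing_mode == "left_censor") {
        order(ab[, j])[seq_len(n_miss_col)]
      } else {
        sample.int(nrow(ab), n_miss_col)
      }
      ab[idx, j] <- NA_real_
    }
  }

  md <- data.frame(
    sample_id = ids,
    gender = config$gender,
    stage = stage,
    # bone-turnover markers: pure noise covariates for baseline classifiers
    osteocalcin = exp(stats::rnorm(3 * n, 2.5, 0.3)),
    PINP = exp(stats::rnorm(3 * n, 3.5, 0.35)),
    bCTX = exp(stats::rnorm(3 * n, -0.7, 0.4)),
    TFFM = stats::rnorm(3 * n, 42, 5),
    age = round(stats::rnorm(3 * n, 62, 6)),
    BMI = stats::rnorm(3 * n, 24, 3),
    stringsAsFactors = FALSE
  )

  null_regime <- length(unique(config$rho_in)) == 1 &&
    length(unique(config$rho_out)) == 1 &&
    all(config$sd_scale == config$sd_scale[1])
  truth <- list(
    domain_members = domain,
    trend_members = trend,
    trend_direction = stats::setNames(
      rep(if (config$trend_step >= 0) "increasing" else "decreasing",
          length(trend)),
      trend
    ),
    null_regime = null_regime,
    stage_params = list(
      rho_in = config$rho_in, rho_out = config$rho_out,
      sd_scale = config$sd_scale
    ),
    seed = seed
  )
  list(cohort = cohort(ab, md), truth = truth)
}

#' Generate exposure/mediator/binary-outcome data with known indirect effect
#'
#' The generative chain is: exposure X ~ N(0,1); mediator
#' M = alpha*X + e, e ~ N(0,1); P(Y=1) = logistic(gamma*X + beta*M). The
#' true average causal mediation effect (ACME) on the risk-difference scale
#' is computed by numeric integration of the potential-outcome contrast at
#' exposure levels mean +/- 1 SD and stored in the truth table, providing an
#' oracle for the estimator in [mediate()].
#'
#' @param config an [sim_config()] whose `mediation` element supplies
#'   `alpha`, `beta`, `gamma`.
#' @param n number of observations (default 500).
#' @param seed overrides `config$seed` when given.
#' @return list with numeric `exposure`, `mediator`, integer 0/1 `outcome`,
#'   and `truth` (generative coefficients, contrast levels, `true_acme`,
#'   `true_ade`, `true_total`).
#' @export
generate_mediation_data <- function(config = sim_config(), n = 500,
                                    seed = NULL) {
  stopifnot(inherits(config, "ow_sim_config"))
  if (is.null(seed)) seed <- config$seed
  m <- config$mediation
  set.seed(seed)
  x <- stats::rnorm(n)
  med <- m$alpha * x + stats::rnorm(n)
  pr <- stats::plogis(m$gamma * x + m$beta * med)
  y <- stats::rbinom(n, 1, pr)
  x0 <- -1
  x1 <- 1
  tr <- true_mediation_effects(m$alpha, m$beta, m$gamma, x0 = x0, x1 = x1)
  list(
    exposure = x, mediator = med, outcome = y,
    truth = c(m, list(
      x0 = x0, x1 = x1,
      true_acme = tr$acme, true_ade = tr$ade, true_total = tr$total
    ))
  )
}

#' True mediation effects by numeric integration
#'
#' For the generative model of [generate_mediation_data()], the expected
#' outcome under exposure set to `x` with the mediator drawn at exposure
#' level `x'` is `E_e[logistic(gamma*x + beta*(alpha*x' + e))]` with
#' `e ~ N(0, sd_m)`. ACME, ADE and the total effect on the probability
#' scale follow from this integral at the four (x, x') combinations,
#' averaged over the two exposure levels.
#'
#' @param alpha,beta,gamma generative coefficients.
#' @param x0,x1 control/treatment exposure levels.
#' @param sd_m mediator residual SD.
#' @return list with `acme`, `ade`, `total`.
#' @export
true_mediation_effects <- function(alpha, beta, gamma, x0 = -1, x1 = 1,
                                   sd_m = 1) {
  pbar <- function(x, xprime) {
    f <- function(e) {
      stats::plogis(gamma * x + beta * (alpha * xprime + e)) *
        stats::dnorm(e, sd = sd_m)
    }
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  }
  p11 <- pbar(x1, x1)
  p10 <- pbar(x1, x0)
  p01 <- pbar(x0, x1)
  p00 <- pbar(x0, x0)
  acme <- ((p11 - p10) + (p01 - p00)) / 2
  ade <- ((p11 - p01) + (p10 - p00)) / 2
  list(acme = acme, ade = ade, total = p11 - p00)
}

#' Write a synthetic cohort to delimited files
#'
#' Emits the same CSV dialect [load_cohort()] reads plus the ground truth as
#' JSON, so a generated cohort can round-trip through the file interface.
#'
#' @param sim result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ab_path <- file.path(dir, "abundance.csv")
  md_path <- file.path(dir, "metadata.csv")
  tt_path <- file.path(dir, "truth.json")
  ab <- data.frame(
    sample_id = rownames(sim$cohort$abundance),
    sim$cohort$abundance,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.csv(ab, ab_path, row.names = FALSE, na = "")
  md <- sim$cohort$metadata
  md$stage <- as.character(md$stage)
  utils::write.csv(md, md_path, row.names = FALSE, na = "")
  jsonlite::write_json(sim$truth, tt_path, auto_unbox = TRUE, digits = NA)
  invisible(c(abundance = ab_path, metadata = md_path, truth = tt_path))
}
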