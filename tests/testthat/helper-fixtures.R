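# Small in-code fixtures shared across the suite.

# cohort with explicit abundances and stage labels
tiny_cohort <- function(ab, stage = NULL, gender = "female") {
  md <- data.frame(sample_id = rownames(ab), gender = gender,
                   stringsAsFactors = FALSE)
  if (!is.null(stage)) md$stage <- stage
  cohort(ab, md)
}

# samples drawn iid from planted correlation blocks plus independent noise;
# simulated on the log scale with a small SD so exponentiation barely
# perturbs the planted correlations
make_block_cohort <- function(n = 100, block_sizes = c(5, 5), rho = 0.8,
                              n_noise = 20, seed = 1) {
  set.seed(seed)
  p <- sum(block_sizes) + n_noise
  R <- diag(p)
  at <- 0
  truth <- rep("grey", p)
  for (b in seq_along(block_sizes)) {
    ix <- at + seq_len(block_sizes[b])
    R[ix, ix] <- rho
    diag(R)[ix] <- 1
    truth[ix] <- paste0("block", b)
    at <- at + block_sizes[b]
  }
  ab <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = R)
  dimnames(ab) <- list(sprintf("S%03d", 1:n), sprintf("M%03d", 1:p))
  list(cohort = tiny_cohort(exp(0.25 * ab)), truth = truth)
}

# reference object built by hand (bypasses build_reference)
manual_reference <- function(mu, sigma, ref_ids = c("r1", "r2", "r3")) {
  structure(
    list(mu = mu, sigma = sigma, reference_ids = ref_ids,
         dropped = character(0), reference_stage = "control"),
    class = "ow_reference"
  )
}

# a staged three-group cohort straight from the generator, imputed
staged_cohort <- function(seed = 1, config = sim_config()) {
  sim <- generate_cohort(config, seed = seed)
  list(cohort = suppressWarnings(filter_missing(sim$cohort)),
       truth = sim$truth)
}

# flat generator settings: no DNB, no trend
null_sim_config <- function(...) {
  sim_config(
    rho_in = rep(0.2, 3), rho_out = rep(0.1, 3), sd_scale = rep(1, 3),
    n_trend = 0, ...
  )
}

# two-class feature-selection setting: 5 informative metabolites shifted by
# 1.0 log-SD between adjacent stages, the rest uninformative
rf_sim_config <- function(...) {
  args <- list(
    n_per_stage = 80, n_metabolites = 20, domain_size = 2,
    rho_in = rep(0.1, 3), rho_out = rep(0.1, 3), sd_scale = rep(1, 3),
    n_trend = 5, trend_step = 1.0, missing_fraction = 0
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# independent exact one-sided Mann-Whitney p via full enumeration
mw_exact_p_greater <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  u_obs <- sum(outer(a, b, "<")) + 0.5 * sum(outer(a, b, "=="))
  idx <- utils::combn(n, length(a))
  us <- apply(idx, 2, function(ix) {
    aa <- pooled[ix]; bb <- pooled[-ix]
    sum(outer(aa, bb, "<")) + 0.5 * sum(outer(aa, bb, "=="))
  })
  mean(us >= u_obs - 1e-9)
}
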