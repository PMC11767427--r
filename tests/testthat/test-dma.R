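test_that("Jonckheere-Terpstra matches exact enumeration on the extremes", {
  up <- jonckheere_terpstra(
    list(c(1, 2), c(3, 4), c(5, 6)), alternative = "increasing"
  )
  expect_equal(up$statistic, 12)
  expect_equal(up$p_value, 1 / 90, tolerance = 1e-12)

  down <- jonckheere_terpstra(
    list(c(5, 6), c(3, 4), c(1, 2)), alternative = "increasing"
  )
  expect_equal(down$statistic, 0)
  expect_equal(down$p_value, 1)

  const <- jonckheere_terpstra(
    list(c(2, 2), c(2, 2), c(2, 2)), alternative = "two_sided"
  )
  expect_equal(const$p_value, 1)
  expect_error(jonckheere_terpstra(list(1:3, numeric(0))), "empty")
})

test_that("JT with two groups reduces to the one-sided Mann-Whitney test", {
  set.seed(31)
  for (i in 1:8) {
    a <- round(runif(sample(2:4, 1)) * 100)
    b <- round(runif(sample(2:4, 1)) * 100)
    if (anyDuplicated(c(a, b))) next
    jt <- jonckheere_terpstra(list(a, b), alternative = "increasing")
    expect_equal(jt$p_value, mw_exact_p_greater(a, b), tolerance = 1e-12)
  }
})

test_that("JT p-values are invariant under strictly increasing transforms", {
  set.seed(32)
  g <- list(rnorm(15), rnorm(15, 0.4), rnorm(15, 0.8))
  p0 <- jonckheere_terpstra(g, "two_sided")$p_value
  for (f in list(exp, function(x) x^3, function(x) 5 * x - 2)) {
    expect_equal(
      jonckheere_terpstra(lapply(g, f), "two_sided")$p_value, p0
    )
  }
})

test_that("Wilcoxon rank-sum matches exact references and handles ties", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(1, 2)$p_value, 1)
  expect_equal(wilcoxon_rank_sum(c(3, 1, 2), c(2, 3, 1))$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty")
})

test_that("run_dma recovers planted trend metabolites and separates stages", {
  cfg <- sim_config(trend_step = 0.8, missing_fraction = 0)
  sim <- generate_cohort(cfg, seed = 3)
  res <- run_dma(sim$cohort)
  hits <- intersect(res$significant_trend, sim$truth$trend_members)
  expect_gte(length(hits), 7L)
  expect_true(all(
    res$trend_table$direction[
      res$trend_table$metabolite %in% hits
    ] == "increasing"
  ))
  expect_true(all(res$trend_table$p >= 0, res$trend_table$p <= 1))
  expect_equal(
    sort(unique(res$pairwise_table$contrast)),
    sort(c("ctrl-vs-open", "ctrl-vs-op", "open-vs-op"))
  )
})

test_that("run_dma false positives under the null stay near alpha * m", {
  sim <- generate_cohort(null_sim_config(missing_fraction = 0), seed = 8)
  res <- run_dma(sim$cohort)
  # 60 metabolites at alpha = .05: 3 expected, 10 is ~3.5 SD above
  expect_lte(length(res$significant_trend), 10L)
})

test_that("a hugely shifted metabolite is significant in all three contrasts", {
  set.seed(41)
  n <- 20
  ab <- matrix(rlnorm(3 * n * 5), 3 * n, 5,
    dimnames = list(sprintf("s%02d", 1:(3 * n)), paste0("m", 1:5))
  )
  stage <- rep(c("control", "osteopenia", "osteoporosis"), each = n)
  ab[, "m3"] <- ab[, "m3"] * c(1, 50, 2500)[match(stage, unique(stage))]
  res <- run_dma(tiny_cohort(ab, stage))
  expect_true(all(vapply(
    res$significant_pairwise, function(s) "m3" %in% s, logical(1)
  )))
})

test_that("PCA ordination captures a rank-1 pattern and ignores column order", {
  set.seed(51)
  u <- rnorm(30)
  v <- runif(8, 0.5, 2)
  ab <- exp(outer(u, v) + matrix(rnorm(240, sd = 1e-3), 30, 8))
  dimnames(ab) <- list(sprintf("s%02d", 1:30), paste0("m", 1:8))
  coh <- tiny_cohort(log(ab))
  sc <- ordination(coh, "pca")
  expect_gt(attr(sc, "explained_variance")[1], 0.99)

  perm <- sample(8)
  coh2 <- tiny_cohort(log(ab)[, perm])
  sc2 <- ordination(coh2, "pca")
  expect_equal(abs(sc$comp1), abs(sc2$comp1), tolerance = 1e-8)
  expect_error(ordination(coh, n_components = 99), "exceeds")
})

test_that("PLS-DA separates stages planted far apart", {
  set.seed(52)
  n <- 15
  stage <- rep(c("control", "osteopenia", "osteoporosis"), each = n)
  shift <- c(control = 0, osteopenia = 4, osteoporosis = 8)[stage]
  ab <- exp(matrix(rnorm(3 * n * 10, sd = 0.5), 3 * n, 10) + shift)
  dimnames(ab) <- list(sprintf("s%02d", 1:(3 * n)), paste0("m", 1:10))
  sc <- ordination(tiny_cohort(ab, stage), "plsda", log_transform = TRUE)
  cent <- aggregate(sc[, c("comp1", "comp2")], list(stage = sc$stage), mean)
  between <- min(dist(cent[, -1]))
  within <- max(tapply(sc$comp1, sc$stage, sd), tapply(sc$comp2, sc$stage, sd))
  expect_gt(between, within)
})
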