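#' Jonckheere-Terpstra test for an ordered trend across groups
#'
#' Tests the null of identical distributions against an ordered alternative
#' over k groups. The statistic is the sum over ordered group pairs (i < j)
#' of Mann-Whitney counts, with ties counted one half:
#' `J = sum_{i<j} [#(x_i < x_j) + 0.5 * #(x_i == x_j)]`. Large J favours an
#' increasing trend. The p-value uses the normal approximation with the
#' tie-corrected null variance; when the pooled sample size is at most 12
#' (or `exact = TRUE`), the exact permutation distribution of J is
#' enumerated instead.
#'
#' The test depends on the data only through ranks, so it is invariant
#' under strictly increasing transformations.
#'
#' @param groups list of numeric vectors in hypothesised order.
#' @param alternative `"two_sided"`, `"increasing"` or `"decreasing"`.
#' @param exact force (TRUE) or suppress (FALSE) exact enumeration; default
#'   NULL enumerates when total n <= 12.
#' @return list with `statistic` (J), `z`, `p_value`, `method`.
#' @export
jonckheere_terpstra <- function(groups,
                                alternative = c(
                                  "two_sided", "increasing", "decreasing"
                                ),
                                exact = NULL) {
  alternative <- match.arg(alternative)
  if (!is.list(groups) || length(groups) < 2) {
    stop("groups must be a list of >= 2 numeric vectors")
  }
  if (any(vapply(groups, length, 1L) == 0)) stop("empty group")
  sizes <- vapply(groups, length, 1L)
  n <- sum(sizes)
  pooled <- unlist(groups, use.names = FALSE)
  if (is.null(exact)) exact <- n <= 12
  jstat <- jt_statistic(groups)

  if (length(unique(pooled)) == 1) {
    return(list(
      statistic = jstat, z = 0,
      p_value = 1, method = "degenerate"
    ))
  }

  if (exact) {
    dist <- jt_exact_distribution(pooled, sizes)
    eps <- 1e-9
    p_ge <- mean(dist >= jstat - eps)
    p_le <- mean(dist <= jstat + eps)
    p <- switch(alternative,
      increasing = p_ge,
      decreasing = p_le,
      two_sided = min(1, 2 * min(p_ge, p_le))
    )
    return(list(
      statistic = jstat, z = NA_real_, p_value = p,
      method = "exact"
    ))
  }

  mu <- (n^2 - sum(sizes^2)) / 4
  tj <- table(pooled)
  v1 <- n * (n - 1) * (2 * n + 5) -
    sum(sizes * (sizes - 1) * (2 * sizes + 5)) -
    sum(tj * (tj - 1) * (2 * tj + 5))
  v2 <- sum(sizes * (sizes - 1) * (sizes - 2)) *
    sum(tj * (tj - 1) * (tj - 2))
  v3 <- sum(sizes * (sizes - 1)) * sum(tj * (tj - 1))
  v <- v1 / 72 + v2 / (36 * n * (n - 1) * (n - 2)) +
    v3 / (8 * n * (n - 1))
  if (v <= 0) {
    return(list(statistic = jstat, z = 0, p_value = 1, method = "degenerate"))
  }
  z <- (jstat - mu) / sqrt(v)
  p <- switch(alternative,
    increasing = stats::pnorm(z, lower.tail = FALSE),
    decreasing = stats::pnorm(z),
    two_sided = min(1, 2 * stats::pnorm(-abs(z)))
  )
  list(statistic = jstat, z = z, p_value = p, method = "normal")
}

jt_statistic <- function(groups) {
  k <- length(groups)
  j <- 0
  for (a in seq_len(k - 1)) {
    for (b in seq(a + 1, k)) {
      cmp <- outer(groups[[a]], groups[[b]], "<")
      tie <- outer(groups[[a]], groups[[b]], "==")
      j <- j + sum(cmp) + 0.5 * sum(tie)
    }
  }
  j
}

# Exact permutation distribution of J: every split of the pooled values
# into groups of the given sizes, enumerated recursively.
jt_exact_distribution <- function(pooled, sizes) {
  n <- length(pooled)
  res <- numeric(0)
  recurse <- function(avail_idx, gi, assigned) {
    if (gi > length(sizes)) {
      groups <- lapply(assigned, function(ix) pooled[ix])
      res[[length(res) + 1]] <<- jt_statistic(groups)
      return(invisible())
    }
    if (gi == length(sizes)) {
      recurse(integer(0), gi + 1L, c(assigned, list(avail_idx)))
      return(invisible())
    }
    picks <- utils::combn(avail_idx, sizes[gi], simplify = FALSE)
    for (pk in picks) {
      recurse(setdiff(avail_idx, pk), gi + 1L, c(assigned, list(pk)))
    }
  }
  recurse(seq_len(n), 1L, list())
  unlist(res)
}

#' Wilcoxon rank-sum test between two groups
#'
#' Two-sided rank-sum (Mann-Whitney) test with midranks for ties. The exact
#' distribution is used when the smaller group has at most 8 observations
#' and there are no ties; otherwise the tie-corrected normal approximation
#' with continuity correction applies.
#'
#' @param a,b nonempty numeric vectors.
#' @return list with `statistic` (Mann-Whitney W for `a`), `p_value`,
#'   `method`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty vector")
  ties <- any(duplicated(c(a, b)))
  use_exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)
  )
  list(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    method = if (use_exact) "exact" else "normal"
  )
}

#' Differential metabolite analysis across the three disease stages
#'
#' For every metabolite: a Jonckheere-Terpstra trend test across the
#' ordered stages (control, osteopenia, osteoporosis) and Wilcoxon rank-sum
#' tests for each of the three stage pairs. Significance uses raw p-values
#' at `alpha` (no multiplicity correction by default, matching common
#' practice in targeted metabolomics screens); `p_adjust = "BH"` switches
#' the significance calls to Benjamini-Hochberg adjusted p-values.
#'
#' @param x staged, filtered, imputed `ow_cohort`.
#' @param alpha significance level (default 0.05).
#' @param p_adjust `"none"` or `"BH"`.
#' @return list of class `ow_dma`: `trend_table` (metabolite, statistic, z,
#'   p, direction), `pairwise_table` (metabolite, contrast, statistic, p),
#'   `significant_trend`, `significant_pairwise` (list by contrast), and
#'   `alpha`.
#' @export
run_dma <- function(x, alpha = 0.05, p_adjust = c("none", "BH")) {
  stopifnot(inherits(x, "ow_cohort"))
  p_adjust <- match.arg(p_adjust)
  st <- cohort_stage(x)
  if (any(table(st) < 2)) stop("every stage needs >= 2 samples")
  if (anyNA(x$abundance)) stop("run filter_missing() with imputation first")
  mets <- colnames(x$abundance)
  lv <- stage_levels()
  contrasts <- list(
    `ctrl-vs-open` = lv[c(1, 2)],
    `ctrl-vs-op` = lv[c(1, 3)],
    `open-vs-op` = lv[c(2, 3)]
  )
  trend <- data.frame(
    metabolite = mets, statistic = NA_real_, z = NA_real_, p = NA_real_,
    direction = NA_character_, stringsAsFactors = FALSE
  )
  pw <- expand.grid(
    metabolite = mets, contrast = names(contrasts),
    stringsAsFactors = FALSE
  )
  pw$statistic <- NA_real_
  pw$p <- NA_real_
  for (i in seq_along(mets)) {
    v <- x$abundance[, i]
    gr <- split(v, st)
    jt <- jonckheere_terpstra(gr, alternative = "two_sided", exact = FALSE)
    trend$statistic[i] <- jt$statistic
    trend$z[i] <- jt$z
    trend$p[i] <- jt$p_value
    trend$direction[i] <- if (isTRUE(jt$z < 0)) "decreasing" else "increasing"
    for (cn in names(contrasts)) {
      wt <- wilcoxon_rank_sum(
        gr[[contrasts[[cn]][1]]], gr[[contrasts[[cn]][2]]]
      )
      row <- pw$metabolite == mets[i] & pw$contrast == cn
      pw$statistic[row] <- wt$statistic
      pw$p[row] <- wt$p_value
    }
  }
  trend_p <- if (p_adjust == "BH") stats::p.adjust(trend$p, "BH") else trend$p
  sig_trend <- trend$metabolite[trend_p < alpha]
  sig_pw <- lapply(names(contrasts), function(cn) {
    sub <- pw[pw$contrast == cn, ]
    pp <- if (p_adjust == "BH") stats::p.adjust(sub$p, "BH") else sub$p
    sub$metabolite[pp < alpha]
  })
  names(sig_pw) <- names(contrasts)
  structure(
    list(
      trend_table = trend, pairwise_table = pw,
      significant_trend = sig_trend, significant_pairwise = sig_pw,
      alpha = alpha, p_adjust = p_adjust
    ),
    class = "ow_dma"
  )
}

#' Ordination of samples by PCA or PLS-DA
#'
#' Metabolites are standardized to zero mean and unit SD (constant columns
#' dropped with a warning); optionally log-transformed first. PCA scores
#' come from the singular value decomposition; PLS-DA scores from a
#' partial-least-squares fit against one-hot stage labels (two components
#' by default, for two-dimensional score plots).
#'
#' @param x filtered, imputed `ow_cohort`; stage labels required for
#'   `method = "plsda"`.
#' @param method `"pca"` or `"plsda"`.
#' @param n_components number of score dimensions.
#' @param log_transform log-transform abundances before scaling.
#' @return data.frame: `sample_id`, `comp1..compk`, `stage` (when present),
#'   with the per-component explained variance as attribute
#'   `"explained_variance"` for PCA.
#' @export
ordination <- function(x, method = c("pca", "plsda"), n_components = 2,
                       log_transform = FALSE) {
  stopifnot(inherits(x, "ow_cohort"))
  method <- match.arg(method)
  ab <- x$abundance
  if (anyNA(ab)) stop("run filter_missing() with imputation first")
  if (n_components > min(dim(ab))) {
    stop("n_components exceeds min(n_samples, n_metabolites)")
  }
  if (log_transform) ab <- log(ab)
  sds <- apply(ab, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant metabolite(s) dropped")
    ab <- ab[, sds > 0, drop = FALSE]
  }
  z <- scale(ab)
  if (method == "pca") {
    pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
    scores <- pc$x[, seq_len(n_components), drop = FALSE]
    expl <- pc$sdev^2 / sum(pc$sdev^2)
  } else {
    st <- cohort_stage(x)
    fit <- mixOmics::plsda(z, factor(st, ordered = FALSE),
      ncomp = n_components, scale = FALSE
    )
    scores <- fit$variates$X[, seq_len(n_components), drop = FALSE]
    expl <- NULL
  }
  out <- data.frame(
    sample_id = rownames(ab), scores,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  names(out)[1 + seq_len(n_components)] <- paste0("comp", seq_len(n_components))
  if ("stage" %in% names(x$metadata)) out$stage <- x$metadata$stage
  rownames(out) <- NULL
  if (!is.null(expl)) attr(out, "explained_variance") <- expl
  out
}
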