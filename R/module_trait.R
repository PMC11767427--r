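#' Soft-threshold adjacency and topological overlap
#'
#' Weighted-correlation-network building blocks: the unsigned adjacency
#' `a_ij = |cor(i, j)|^beta` (signed variant:
#' `((1 + cor)/2)^beta`), and the topological overlap matrix
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu` (self terms excluded). Both lie in `[0, 1]`; TOM of a
#' connectionless network is zero off the diagonal.
#'
#' @param ab samples x metabolites abundance matrix.
#' @param beta soft-thresholding power (> 0; default 6).
#' @param signed use the signed adjacency.
#' @return adjacency or TOM similarity matrix.
#' @export
wgcna_adjacency <- function(ab, beta = 6, signed = FALSE) {
  if (beta <= 0) stop("beta must be positive")
  r <- stats::cor(ab)
  a <- if (signed) ((1 + r) / 2)^beta else abs(r)^beta
  diag(a) <- 0
  a
}

#' @rdname wgcna_adjacency
#' @param adjacency adjacency matrix with zero diagonal.
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  k <- rowSums(a)
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom
}

#' Co-abundance modules by topological-overlap clustering
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut statically at
#' `cut_height`; clusters of at least `min_size` metabolites become
#' modules, everything else is pooled as `"grey"` (unassigned). Modules
#' receive the conventional color labels in decreasing size order, so
#' labelling is deterministic. (A static cut is used instead of dynamic
#' hybrid tree cutting; the cut height is tunable.)
#'
#' @param x filtered, imputed `ow_cohort`.
#' @param beta soft power (default 6).
#' @param cut_height static cut height on the `1 - TOM` scale (default
#'   0.9).
#' @param min_size minimum module size (default 5).
#' @param signed use signed adjacency.
#' @return list with `assignments` (data.frame metabolite/module_color)
#'   and `modules` (named list of member vectors, grey excluded).
#' @export
wgcna_modules <- function(x, beta = 6, cut_height = 0.9, min_size = 5,
                          signed = FALSE) {
  stopifnot(inherits(x, "ow_cohort"))
  if (anyNA(x$abundance)) stop("run filter_missing() with imputation first")
  ab <- x$abundance
  sds <- apply(ab, 2, stats::sd)
  ab <- ab[, sds > 0, drop = FALSE]
  if (ncol(ab) < min_size) stop("fewer metabolites than min_size")
  tom <- tom_similarity(wgcna_adjacency(ab, beta = beta, signed = signed))
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  good <- names(sizes)[sizes >= min_size]
  palette <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan"
  )
  ord <- good[order(-sizes[good], good)]
  color <- stats::setNames(rep("grey", ncol(ab)), colnames(ab))
  modules <- list()
  for (i in seq_along(ord)) {
    lab <- if (i <= length(palette)) palette[i] else paste0("module", i)
    members <- colnames(ab)[cl == ord[i]]
    color[members] <- lab
    modules[[lab]] <- members
  }
  list(
    assignments = data.frame(
      metabolite = names(color), module_color = unname(color),
      stringsAsFactors = FALSE
    ),
    modules = modules
  )
}

#' Eigen-metabolite of a module
#'
#' First principal component of the module members' standardized
#' abundances, sign-oriented so that its correlation with the mean
#' standardized module abundance is non-negative. It is the best single
#' summary of the module: it explains at least as much variance as any
#' individual member.
#'
#' @param ab samples x metabolites abundance matrix.
#' @param members module member ids.
#' @return numeric vector (one value per sample).
#' @export
eigen_metabolite <- function(ab, members) {
  z <- scale(ab[, members, drop = FALSE])
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  e <- pc$x[, 1]
  if (stats::cor(e, rowMeans(z)) < 0) e <- -e
  e
}

#' Module-trait and biomarker-trait correlation table
#'
#' Pearson correlation (with two-sided p-value) between each row entity --
#' a module's eigen-metabolite or an individual biomarker metabolite's
#' abundance -- and each numeric clinical trait. Missing trait values are
#' handled pairwise-complete; cells with fewer than `min_pairs` complete
#' pairs, or a constant trait, are flagged NA.
#'
#' @param x filtered, imputed `ow_cohort`.
#' @param traits data.frame of numeric traits, one row per sample, aligned
#'   to the cohort samples (or carrying a `sample_id` column).
#' @param modules named list of module member vectors (rows are modules),
#'   or NULL.
#' @param features metabolite ids (rows are single metabolites), or NULL.
#'   At least one of `modules`/`features` must be given.
#' @param min_pairs minimum complete pairs per cell (default 3).
#' @param alpha significance level for the `significant` flag.
#' @return data.frame of class `ow_trait_table`: `row_id`, `row_type`,
#'   `trait`, `r`, `p`, `n`, `significant`.
#' @export
trait_correlations <- function(x, traits, modules = NULL, features = NULL,
                               min_pairs = 3, alpha = 0.05) {
  stopifnot(inherits(x, "ow_cohort"))
  if (is.null(modules) && is.null(features)) {
    stop("give modules and/or features")
  }
  traits <- as.data.frame(traits)
  if ("sample_id" %in% names(traits)) {
    traits <- traits[match(rownames(x$abundance), traits$sample_id), , drop = FALSE]
    traits$sample_id <- NULL
  }
  if (nrow(traits) != nrow(x$abundance)) {
    stop("traits rows do not align with cohort samples")
  }
  row_vecs <- list()
  row_type <- character(0)
  for (nm in names(modules)) {
    row_vecs[[nm]] <- eigen_metabolite(x$abundance, modules[[nm]])
    row_type[nm] <- "module"
  }
  for (f in features) {
    row_vecs[[f]] <- x$abundance[, f]
    row_type[f] <- "biomarker"
  }
  out <- expand.grid(
    row_id = names(row_vecs), trait = names(traits),
    stringsAsFactors = FALSE
  )
  out$row_type <- row_type[out$row_id]
  out$r <- NA_real_
  out$p <- NA_real_
  out$n <- NA_integer_
  for (i in seq_len(nrow(out))) {
    v <- row_vecs[[out$row_id[i]]]
    tr <- as.numeric(traits[[out$trait[i]]])
    ok <- stats::complete.cases(v, tr)
    out$n[i] <- sum(ok)
    if (sum(ok) < min_pairs || stats::sd(tr[ok]) == 0 ||
        stats::sd(v[ok]) == 0) next
    ct <- stats::cor.test(v[ok], tr[ok], method = "pearson")
    out$r[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  out$significant <- !is.na(out$p) & out$p < alpha
  class(out) <- c("ow_trait_table", "data.frame")
  out
}
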