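#' Reference statistics from the healthy (control) stage
#'
#' All single-sample network quantities are anchored to the control group:
#' each metabolite's reference mean and SD standardize the sample's
#' deviation, so every downstream score is invariant to affine rescaling of
#' individual metabolites (unit changes). Metabolites with zero reference
#' variance cannot be standardized and are dropped with a warning.
#'
#' @param x staged `ow_cohort` without missing cells.
#' @param reference_stage stage providing the reference samples (default
#'   `"control"`); at least 3 samples required.
#' @return `ow_reference`: list with `mu`, `sigma` (named vectors over
#'   retained metabolites), `reference_ids`, `dropped`.
#' @export
build_reference <- function(x, reference_stage = "control") {
  stopifnot(inherits(x, "ow_cohort"))
  if (anyNA(x$abundance)) stop("run filter_missing() with imputation first")
  st <- cohort_stage(x)
  ref_ids <- rownames(x$abundance)[st == reference_stage]
  if (length(ref_ids) < 3) {
    stop("need >= 3 reference samples, got ", length(ref_ids))
  }
  ra <- x$abundance[ref_ids, , drop = FALSE]
  mu <- colMeans(ra)
  sigma <- apply(ra, 2, stats::sd)
  dropped <- names(sigma)[sigma == 0]
  if (length(dropped) > 0) {
    warning(
      "dropping ", length(dropped),
      " zero-variance metabolite(s) in the reference: ",
      paste(utils::head(dropped, 5), collapse = ", ")
    )
    mu <- mu[sigma > 0]
    sigma <- sigma[sigma > 0]
  }
  structure(
    list(
      mu = mu, sigma = sigma,
      reference_ids = ref_ids, dropped = dropped,
      reference_stage = reference_stage
    ),
    class = "ow_reference"
  )
}

# Reference-standardized deviations for a matrix (samples x metabolites)
# or a single named sample vector; columns restricted to retained
# metabolites. With loo = TRUE, rows that are themselves reference samples
# are standardized against the leave-one-out reference (mean/SD excluding
# that sample), which removes the in-sample attenuation of their
# deviations; other rows are unaffected.
ref_zscores <- function(values, ref, loo = FALSE, absdev = FALSE) {
  if (is.null(dim(values))) {
    values <- matrix(values, 1,
      dimnames = list("sample", names(values))
    )
  }
  miss <- setdiff(names(ref$mu), colnames(values))
  if (length(miss) > 0) {
    stop("values lack reference metabolite(s): ", miss[1])
  }
  v <- values[, names(ref$mu), drop = FALSE]
  dev <- sweep(v, 2, ref$mu, "-")
  sig <- matrix(ref$sigma, nrow(v), ncol(v), byrow = TRUE,
                dimnames = dimnames(v))
  n <- length(ref$reference_ids)
  in_ref <- rownames(v) %in% ref$reference_ids
  if (loo && any(in_ref) && n >= 4) {
    d <- dev[in_ref, , drop = FALSE]
    # mu_{-s} = (n mu - x_s)/(n-1)  =>  x_s - mu_{-s} = n/(n-1) (x_s - mu)
    dev[in_ref, ] <- d * n / (n - 1)
    s2 <- matrix(ref$sigma^2, sum(in_ref), ncol(v), byrow = TRUE)
    loo_var <- ((n - 1) * s2 - d^2 * n / (n - 1)) / (n - 2)
    loo_var <- pmax(loo_var, 1e-12)
    sig[in_ref, ] <- sqrt(loo_var)
  }
  z <- dev / sig
  if (absdev) list(z = z, absdev = abs(dev)) else z
}

#' Single-sample Pearson correlation score (sPCC) of a metabolite pair
#'
#' For sample s and pair (x, y), `sPCC_s(x, y) = z_x(s) * z_y(s)` where
#' `z_m(s) = (value_m(s) - mu_m) / sigma_m` standardizes against the
#' control reference. This is the sample's additive contribution to the
#' reference Pearson correlation: averaging sPCC over the reference samples
#' themselves recovers `(n-1)/n` times their Pearson correlation. The score
#' is symmetric in (x, y) and zero when the sample sits exactly at the
#' reference mean.
#'
#' The `"delta"` variant instead reports the perturbation correlation:
#' Pearson correlation of (x, y) over the reference plus the sample, minus
#' the reference-only correlation. It is provided for sensitivity analysis.
#'
#' @param sample named numeric vector of one sample's abundances.
#' @param ref an [build_reference()] object; for `form = "delta"` it must
#'   retain the raw reference values, see `keep_data` below.
#' @param pair character vector of two metabolite ids.
#' @param form `"product"` (default) or `"delta"`.
#' @param reference_data reference abundance matrix, required for
#'   `form = "delta"`.
#' @return signed numeric score.
#' @export
spcc <- function(sample, ref, pair, form = c("product", "delta"),
                 reference_data = NULL) {
  form <- match.arg(form)
  if (!all(pair %in% names(ref$mu))) {
    stop("metabolite absent from reference: ",
         setdiff(pair, names(ref$mu))[1])
  }
  if (form == "product") {
    z <- ref_zscores(sample, ref)
    return(unname(z[1, pair[1]] * z[1, pair[2]]))
  }
  if (is.null(reference_data)) {
    stop("form = 'delta' needs reference_data")
  }
  r0 <- stats::cor(reference_data[, pair[1]], reference_data[, pair[2]])
  aug <- rbind(
    reference_data[, pair, drop = FALSE],
    sample[pair]
  )
  stats::cor(aug[, 1], aug[, 2]) - r0
}

#' Select top-ranked sPCC edges as the network background
#'
#' Metabolites have no curated interaction network, so the background edge
#' set is taken from the data: all unordered metabolite pairs are ranked by
#' the mean absolute sPCC across the non-reference samples, and the top
#' quantile (default 1%) or top k pairs are retained. Ties are broken by
#' the lexicographic pair id so that selection is deterministic. The
#' per-edge mean and SD of sPCC scores over the reference samples are
#' stored for later standardization in [shpcc()].
#'
#' @param x staged `ow_cohort`.
#' @param ref [build_reference()] object.
#' @param top_quantile fraction of pairs kept (used when `top_k` is NULL).
#' @param top_k number of pairs kept (overrides `top_quantile`).
#' @return `ow_edge_network`: `edges` data.frame (`a`, `b`, `edge_id`,
#'   `mean_abs_spcc`, `ref_mean`, `ref_sd`), `scores` matrix (all samples x
#'   edges, signed sPCC), and the selection `rule`.
#' @export
select_top_edges <- function(x, ref, top_quantile = 0.01, top_k = NULL) {
  stopifnot(inherits(x, "ow_cohort"), inherits(ref, "ow_reference"))
  p <- length(ref$mu)
  if (p < 2) stop("need >= 2 retained metabolites")
  z <- ref_zscores(x$abundance, ref)
  is_ref <- rownames(z) %in% ref$reference_ids
  pairs <- utils::combn(names(ref$mu), 2)
  n_pairs <- ncol(pairs)
  n_keep <- if (!is.null(top_k)) {
    as.integer(top_k)
  } else {
    max(1L, floor(top_quantile * n_pairs))
  }
  if (n_keep < 1 || n_keep > n_pairs) {
    stop("edge selection rule yields ", n_keep, " of ", n_pairs, " edges")
  }
  i1 <- match(pairs[1, ], colnames(z))
  i2 <- match(pairs[2, ], colnames(z))
  scores <- z[, i1, drop = FALSE] * z[, i2, drop = FALSE]
  edge_id <- paste(pairs[1, ], pairs[2, ], sep = "~")
  colnames(scores) <- edge_id
  rank_score <- if (any(!is_ref)) {
    colMeans(abs(scores[!is_ref, , drop = FALSE]))
  } else {
    colMeans(abs(scores))
  }
  ord <- order(-rank_score, edge_id)
  keep <- ord[seq_len(n_keep)]
  ref_scores <- scores[is_ref, keep, drop = FALSE]
  edges <- data.frame(
    a = pairs[1, keep], b = pairs[2, keep],
    edge_id = edge_id[keep],
    mean_abs_spcc = rank_score[keep],
    ref_mean = colMeans(ref_scores),
    ref_sd = apply(ref_scores, 2, stats::sd),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(
      edges = edges,
      scores = scores[, keep, drop = FALSE],
      rule = if (!is.null(top_k)) {
        list(type = "top_k", k = n_keep)
      } else {
        list(type = "top_quantile", q = top_quantile, k = n_keep)
      }
    ),
    class = "ow_edge_network"
  )
}

#' Fourth-order single-sample edge-pair correlation (shPCC)
#'
#' Quantifies the coupling of two edges (two metabolite pairs, hence four
#' metabolite values) in one sample:
#' `shPCC_s(e1, e2) = Z_e1(s) * Z_e2(s)` where `Z_e(s)` standardizes the
#' sample's edge score `sPCC_s(e)` by the mean and SD of that edge's scores
#' over the reference samples. Symmetric in the two edges. Edges whose
#' reference score SD is zero cannot be standardized; they are skipped with
#' a warning (NA returned).
#'
#' @param sample named numeric vector of one sample's abundances.
#' @param edge_pair length-2 character vector of edge ids (`"A~B"` form) or
#'   a list of two metabolite pairs.
#' @param network [select_top_edges()] result.
#' @param ref [build_reference()] object.
#' @return signed numeric score (NA when a reference SD is zero).
#' @export
shpcc <- function(sample, edge_pair, network, ref) {
  stopifnot(inherits(network, "ow_edge_network"))
  if (is.list(edge_pair)) {
    edge_pair <- vapply(
      edge_pair,
      function(p) paste(sort(p), collapse = "~"), character(1)
    )
  }
  ix <- match(edge_pair, network$edges$edge_id)
  if (anyNA(ix)) {
    stop("edge not in network: ", edge_pair[which(is.na(ix))[1]])
  }
  e <- network$edges[ix, ]
  if (any(e$ref_sd == 0)) {
    warning("edge pair skipped: zero reference SD for ",
            e$edge_id[e$ref_sd == 0][1])
    return(NA_real_)
  }
  s1 <- spcc(sample, ref, c(e$a[1], e$b[1]))
  s2 <- spcc(sample, ref, c(e$a[2], e$b[2]))
  z1 <- (s1 - e$ref_mean[1]) / e$ref_sd[1]
  z2 <- (s2 - e$ref_mean[2]) / e$ref_sd[2]
  z1 * z2
}

#' Candidate metabolite modules by correlation clustering
#'
#' Metabolites are clustered by average-linkage hierarchical clustering on
#' the dissimilarity `1 - |Pearson correlation|` over all samples. The tree
#' is cut at `cut_height`; clusters within the size bounds become candidate
#' modules (each metabolite belongs to at most one). When no cluster at
#' that height satisfies the bounds, the cut count k that maximizes the
#' number of in-bounds clusters is used instead, with a warning.
#'
#' @param x filtered, imputed `ow_cohort`.
#' @param min_size,max_size module size bounds (defaults 3 and 30).
#' @param cut_height static cut height on the `1 - |r|` scale (default
#'   0.8).
#' @return named list of character vectors (module members), ordered by
#'   decreasing size.
#' @export
detect_modules <- function(x, min_size = 3, max_size = 30,
                           cut_height = 0.8) {
  stopifnot(inherits(x, "ow_cohort"))
  if (anyNA(x$abundance)) stop("run filter_missing() with imputation first")
  ab <- x$abundance
  sds <- apply(ab, 2, stats::sd)
  ab <- ab[, sds > 0, drop = FALSE]
  p <- ncol(ab)
  if (p < min_size) stop("fewer metabolites than min_size")
  d <- stats::as.dist(1 - abs(stats::cor(ab)))
  hc <- stats::hclust(d, method = "average")
  harvest <- function(cl) {
    sizes <- table(cl)
    good <- names(sizes)[sizes >= min_size & sizes <= max_size]
    mods <- lapply(good, function(g) colnames(ab)[cl == g])
    mods[order(-vapply(mods, length, 1L),
               vapply(mods, function(m) m[1], character(1)))]
  }
  mods <- harvest(stats::cutree(hc, h = cut_height))
  if (length(mods) == 0) {
    counts <- vapply(2:(p - 1), function(k) {
      sizes <- table(stats::cutree(hc, k = k))
      sum(sizes >= min_size & sizes <= max_size)
    }, integer(1))
    if (max(counts) == 0) {
      stop("no candidate module within size bounds at any cut")
    }
    k_best <- (2:(p - 1))[which.max(counts)]
    warning(
      "no module within size bounds at cut_height=", cut_height,
      "; falling back to best k-cut (k=", k_best, ")"
    )
    mods <- harvest(stats::cutree(hc, k = k_best))
  }
  names(mods) <- sprintf("module_%02d", seq_along(mods))
  mods
}

#' Single-sample composite early-warning index (sCI)
#'
#' For a candidate "domain" module D in one sample,
#' `sCI = (mean_{x,y in D} |sPCC(x,y)|) /
#'        (mean_{x in D, y notin D} |sPCC(x,y)|) * mean_{x in D} |x - mu_x|`.
#' The first factor measures intra-domain coupling, the second factor (the
#' denominator) the domain's coupling to everything else, and the third the
#' domain's deviation magnitude from the healthy reference -- together the
#' three dynamic-network-biomarker signatures of an approaching transition.
#' The denominator is floored at `epsilon` (with a flag) so that a fully
#' decoupled domain yields a large finite value, never NaN/Inf.
#'
#' @param sample named numeric vector of one sample's abundances, or a
#'   samples x metabolites matrix (rows scored independently).
#' @param module character vector (>= 2) of in-domain metabolite ids.
#' @param ref [build_reference()] object.
#' @param outside ids forming the out-of-domain universe; defaults to all
#'   retained reference metabolites not in `module`.
#' @param epsilon denominator floor (default 1e-8).
#' @param loo_reference score reference samples against the leave-one-out
#'   reference (default TRUE). Reference samples contribute to their own
#'   mean and SD, which attenuates their apparent deviation relative to
#'   genuinely out-of-reference samples; the leave-one-out correction puts
#'   all stages on the same footing. Rows not named as reference samples
#'   are never affected.
#' @return data.frame with one row per sample: `sci`, `spcc_in`,
#'   `spcc_out`, `ssd_in`, `denominator_floored`.
#' @export
sci <- function(sample, module, ref, outside = NULL, epsilon = 1e-8,
                loo_reference = TRUE) {
  stopifnot(inherits(ref, "ow_reference"))
  if (length(module) < 2) stop("module must have >= 2 members")
  if (!all(module %in% names(ref$mu))) {
    stop("module member absent from reference: ",
         setdiff(module, names(ref$mu))[1])
  }
  if (is.null(outside)) outside <- setdiff(names(ref$mu), module)
  if (length(outside) < 1) stop("no out-of-module metabolites")
  zd <- ref_zscores(sample, ref, loo = loo_reference, absdev = TRUE)
  a <- abs(zd$z)
  m <- length(module)
  a_in <- a[, module, drop = FALSE]
  a_out <- a[, outside, drop = FALSE]
  # |z_x z_y| = |z_x||z_y| factorizes, so pair means reduce to row sums
  s1 <- rowSums(a_in)
  s2 <- rowSums(a_in^2)
  spcc_in <- (s1^2 - s2) / (m * (m - 1))
  spcc_out <- (s1 / m) * rowMeans(a_out)
  ssd_in <- rowMeans(zd$absdev[, module, drop = FALSE])
  floored <- spcc_out < epsilon
  val <- spcc_in / pmax(spcc_out, epsilon) * ssd_in
  data.frame(
    sci = val, spcc_in = spcc_in, spcc_out = spcc_out, ssd_in = ssd_in,
    denominator_floored = floored,
    row.names = rownames(zd$z)
  )
}

#' Detect the critical (tipping-point) stage via the sCI trajectory
#'
#' Runs the full single-sample network analysis: anchors a reference on a
#' held-out subset of the control samples, extracts candidate metabolite
#' modules, computes each out-of-reference sample's sCI for every
#' candidate, aggregates within stage, and selects the module whose best
#' stage aggregate is largest as the "domain" module. The stage at which
#' that module's aggregate sCI peaks is the critical stage -- under the
#' dynamic-network-biomarker premise, the pre-disease state where network
#' coupling and variance surge.
#'
#' Holding the reference out of the staging decision matters: samples that
#' are part of the reference have their reference-estimation noise baked
#' into their own scores, so a decision over (module, stage) maxima would
#' otherwise systematically disfavour the control stage. With the split,
#' every scored sample -- control, osteopenia or osteoporosis -- is
#' equally out-of-reference and the decision is exchangeable across
#' stages when nothing is going on. The reference subset is the first
#' `reference_fraction` of control samples in row order, so the split is
#' deterministic. Reference-subset samples still receive sCI values in the
#' output (scored leave-one-out against their own reference) for
#' trajectory plots, but they do not enter the stage aggregates.
#'
#' @param x staged, filtered, imputed `ow_cohort`.
#' @param ref optional precomputed [build_reference()]; when supplied, its
#'   `reference_ids` define the held-out set and `reference_fraction` is
#'   ignored.
#' @param reference_fraction fraction of control samples anchoring the
#'   reference (default 0.5).
#' @param min_size,max_size,cut_height passed to [detect_modules()].
#' @param aggregate stage aggregator of per-sample sCI, `"mean"` (default)
#'   or `"median"`.
#' @param epsilon denominator floor for [sci()].
#' @return `ow_domain_module`: `members`, per-sample `sci` table for the
#'   domain module (all samples; `in_reference` flag), `stage_means`
#'   (named length-3 vector over scored samples), `critical_stage`,
#'   `candidates` (per-candidate stage aggregates), `n_floored`.
#' @export
detect_critical_stage <- function(x, ref = NULL, reference_fraction = 0.5,
                                  min_size = 3,
                                  max_size = 30, cut_height = 0.8,
                                  aggregate = c("mean", "median"),
                                  epsilon = 1e-8) {
  stopifnot(inherits(x, "ow_cohort"))
  aggregate <- match.arg(aggregate)
  st <- cohort_stage(x)
  if (length(unique(st)) < 3) stop("all three stages must be present")
  ids <- rownames(x$abundance)
  if (is.null(ref)) {
    ctrl <- ids[st == "control"]
    n_ref <- max(3L, ceiling(reference_fraction * length(ctrl)))
    ref_ids <- ctrl[seq_len(min(n_ref, length(ctrl)))]
    sub <- cohort(
      x$abundance[ref_ids, , drop = FALSE],
      x$metadata[x$metadata$sample_id %in% ref_ids, , drop = FALSE]
    )
    ref <- build_reference(sub)
  }
  scored <- setdiff(ids, ref$reference_ids)
  if (length(scored) == 0) stop("no out-of-reference samples to score")
  st_scored <- st[match(scored, ids)]
  if (length(unique(st_scored)) < 3) {
    stop("all three stages must remain after holding out the reference")
  }
  # balance the scored groups: stage aggregates are computed over equally
  # many samples per stage (first n_min in row order), so that under a
  # flat (null) cohort the three aggregates are exchangeable and no stage
  # is favoured by a smaller, noisier group
  n_min <- min(table(st_scored))
  balanced <- unlist(lapply(stage_levels(), function(sv) {
    utils::head(scored[st_scored == sv], n_min)
  }))
  st_bal <- st[match(balanced, ids)]
  mods <- detect_modules(x, min_size = min_size, max_size = max_size,
                         cut_height = cut_height)
  mods <- Filter(function(m) sum(m %in% names(ref$mu)) >= 2, mods)
  if (length(mods) == 0) stop("no candidate module after reference filtering")
  agg_fun <- if (aggregate == "mean") mean else stats::median
  cand <- lapply(mods, function(m) {
    m <- intersect(m, names(ref$mu))
    tab <- sci(x$abundance[balanced, , drop = FALSE], m, ref,
               epsilon = epsilon)
    vapply(
      stage_levels(),
      function(sv) agg_fun(tab$sci[st_bal == sv]), numeric(1)
    )
  })
  cand_mat <- do.call(rbind, cand)
  best <- which.max(apply(cand_mat, 1, max))
  members <- intersect(mods[[best]], names(ref$mu))
  tab <- sci(x$abundance, members, ref, epsilon = epsilon)
  stage_means <- cand_mat[best, ]
  structure(
    list(
      members = members,
      sci = cbind(tab,
        stage = st,
        in_reference = ids %in% ref$reference_ids
      ),
      stage_means = stage_means,
      critical_stage = stage_levels()[which.max(stage_means)],
      candidates = cand_mat,
      aggregate = aggregate,
      reference_ids = ref$reference_ids,
      n_floored = sum(tab$denominator_floored)
    ),
    class = "ow_domain_module"
  )
}

#' @export
print.ow_domain_module <- function(x, ...) {
  cat("Domain module:", length(x$members), "metabolites\n")
  cat("Stage", x$aggregate, "sCI:\n")
  print(round(x$stage_means, 4))
  cat("Critical stage:", x$critical_stage, "\n")
  if (x$n_floored > 0) {
    cat(x$n_floored, "sample(s) had a floored sCI denominator\n")
  }
  invisible(x)
}
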