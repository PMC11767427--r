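#' Configuration for a full pipeline run
#'
#' Bundles every knob of the analysis with defaults matching common
#' practice for this pipeline (20% missingness cut, alpha 0.05, 70/30
#' split, 5% importance cut). Input is either a pair of delimited files or
#' a synthetic-cohort configuration. Every random stage derives its seed
#' deterministically from `seed`, so a config reproduces its outputs
#' byte-for-byte.
#'
#' @param abundance_path,metadata_path input files (NULL to simulate).
#' @param sim [sim_config()] used when no input files are given.
#' @param gender stratum to analyse, or `"pooled"` to ignore gender.
#' @param max_missing_fraction,impute passed to [filter_missing()].
#' @param alpha significance level for DMA and trait tables.
#' @param split_fraction,importance_threshold passed to the
#'   random-forest stage.
#' @param iena list of overrides for [detect_critical_stage()].
#' @param mediation_exposures metadata columns screened as exposures.
#' @param seed master seed.
#' @return classed list (`ow_run_config`).
#' @export
run_config <- function(abundance_path = NULL, metadata_path = NULL,
                       sim = sim_config(),
                       gender = "pooled",
                       max_missing_fraction = 0.20,
                       impute = "median",
                       alpha = 0.05,
                       split_fraction = 0.70,
                       importance_threshold = 0.05,
                       iena = list(),
                       mediation_exposures = c("TFFM", "BMI"),
                       seed = 1L) {
  structure(
    list(
      abundance_path = abundance_path, metadata_path = metadata_path,
      sim = sim, gender = gender,
      max_missing_fraction = max_missing_fraction, impute = impute,
      alpha = alpha, split_fraction = split_fraction,
      importance_threshold = importance_threshold,
      iena = iena,
      mediation_exposures = mediation_exposures,
      seed = as.integer(seed)
    ),
    class = "ow_run_config"
  )
}

#' Run the full early-warning analysis pipeline
#'
#' Stages, in order: load (or simulate) the cohort; missingness filter and
#' imputation; differential metabolite analysis (trend + pairwise tests,
#' PCA/PLS-DA scores); single-sample edge-network analysis with sCI
#' critical-stage detection; random-forest biomarker selection with paired
#' AUC comparison against the bone-turnover-marker baseline; module-trait
#' correlation; mediation screen of clinical exposures through the selected
#' metabolites. Each stage writes its tables under `out_dir`, and a JSON
#' manifest records the configuration, derived seeds, stage record counts
#' and warnings. Re-running an identical config overwrites with identical
#' bytes.
#'
#' @param config an [run_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "ow_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("dma", "iena", "rf", "wgcna", "mediation")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, w)
  run_stage <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(
          "pipeline stage '", stage, "' failed: ", conditionMessage(e),
          " (partial outputs under ", out_dir, ")",
          call. = FALSE
        )
      }),
      warning = function(w) {
        note(paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  }
  wtsv <- function(df, ...) {
    utils::write.table(df, file.path(out_dir, ...),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }

  simulated <- is.null(config$abundance_path)
  coh <- run_stage("load", {
    if (simulated) {
      generate_cohort(config$sim, seed = config$seed)$cohort
    } else {
      load_cohort(config$abundance_path, config$metadata_path)
    }
  })
  if (config$gender != "pooled") {
    if (!"gender" %in% names(coh$metadata)) {
      stop("config requests gender stratum '", config$gender,
           "' but metadata has no gender column")
    }
    keep <- coh$metadata$gender == config$gender
    if (!any(keep)) {
      stop("no samples in gender stratum '", config$gender, "'")
    }
    coh <- cohort(
      coh$abundance[coh$metadata$sample_id[keep], , drop = FALSE],
      coh$metadata[keep, , drop = FALSE]
    )
  }
  coh <- run_stage("filter", filter_missing(
    coh, config$max_missing_fraction, impute = config$impute
  ))
  wtsv(removal_report(coh), "removal_report.tsv")

  dma <- run_stage("dma", run_dma(coh, alpha = config$alpha))
  wtsv(dma$trend_table, "dma", "trend.tsv")
  wtsv(dma$pairwise_table, "dma", "pairwise.tsv")
  for (m in c("pca", "plsda")) {
    sc <- run_stage("dma", ordination(coh, method = m))
    wtsv(sc, "dma", paste0(m, "_scores.tsv"))
  }

  iena_args <- c(list(x = coh), config$iena)
  dom <- run_stage("iena", do.call(detect_critical_stage, iena_args))
  ref <- run_stage("iena", build_reference(coh))
  net <- run_stage("iena", select_top_edges(coh, ref))
  wtsv(
    cbind(sample_id = rownames(dom$sci), dom$sci),
    "iena", "sci_per_sample.tsv"
  )
  wtsv(
    net$edges[, c("a", "b", "mean_abs_spcc")],
    "iena", "edges.tsv"
  )
  jsonlite::write_json(
    list(
      members = dom$members,
      stage_means = as.list(dom$stage_means),
      critical_stage = dom$critical_stage,
      n_floored = dom$n_floored
    ),
    file.path(out_dir, "iena", "domain_module.json"),
    auto_unbox = TRUE, digits = NA
  )

  features <- dma$significant_pairwise[["ctrl-vs-open"]]
  if (length(features) < 2) {
    note("rf: <2 differential metabolites; using all metabolites")
    features <- colnames(coh$abundance)
  }
  split <- run_stage("rf", split_train_test(
    coh, fraction = config$split_fraction, seed = config$seed + 101L
  ))
  panel <- run_stage("rf", train_select_retrain(
    coh, features,
    split = split,
    threshold = config$importance_threshold, seed = config$seed + 101L
  ))
  cmp <- run_stage("rf", {
    base <- btm_baseline(coh, split, seed = config$seed + 101L)
    compare_auc(panel$test_labels, panel$test_scores, base$test_scores)
  })
  wtsv(panel$roc, "rf", "roc.tsv")
  jsonlite::write_json(
    list(
      selected = panel$selected,
      importance_percent = as.list(round(panel$importance, 6)),
      auc = panel$auc, auc_ci = as.list(panel$auc_ci),
      vs_btm = list(
        delta_auc = cmp$delta_auc, p_value = cmp$p_value,
        method = cmp$method
      )
    ),
    file.path(out_dir, "rf", "panel.json"),
    auto_unbox = TRUE, digits = NA
  )

  wg <- run_stage("wgcna", wgcna_modules(coh))
  wtsv(wg$assignments, "wgcna", "modules.tsv")
  trait_cols <- intersect(
    c(config$mediation_exposures, "age", "osteocalcin", "PINP", "bCTX"),
    names(coh$metadata)
  )
  if (length(wg$modules) > 0 && length(trait_cols) > 0) {
    tt <- run_stage("wgcna", trait_correlations(
      coh, coh$metadata[, trait_cols, drop = FALSE],
      modules = wg$modules, features = panel$selected,
      alpha = config$alpha
    ))
    wtsv(as.data.frame(tt), "wgcna", "trait_correlations.tsv")
  }

  exposures <- intersect(config$mediation_exposures, names(coh$metadata))
  med <- NULL
  if (length(exposures) > 0) {
    med <- run_stage("mediation", mediate_screen(
      coh, exposures, panel$selected, seed = config$seed + 202L
    ))
    wtsv(med, "mediation", "screen.tsv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("osteowarn")),
    config = unclass_config(config),
    simulated = simulated,
    n_samples = nrow(coh$abundance),
    n_metabolites = ncol(coh$abundance),
    derived_seeds = list(
      cohort = config$seed, rf = config$seed + 101L,
      mediation = config$seed + 202L
    ),
    critical_stage = dom$critical_stage,
    n_selected_biomarkers = length(panel$selected),
    warnings = warnings_log
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(
    cohort = coh, dma = dma, domain = dom, panel = panel,
    auc_comparison = cmp, wgcna = wg, mediation = med,
    manifest = manifest
  ))
}

unclass_config <- function(config) {
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  cfg
}
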