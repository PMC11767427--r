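#' Metabolomic cohort container
#'
#' A cohort bundles a samples x metabolites abundance matrix with per-sample
#' metadata. Abundances are non-negative concentrations (uM or semi-quantified
#' units); missing cells are allowed until [filter_missing()] has been applied.
#' Metadata must carry a `sample_id` column; a `stage` column with the three
#' ordered disease levels (control, osteopenia, osteoporosis) is required by
#' most downstream stages and can be computed from per-site bone-density
#' T-scores via [assign_stage()].
#'
#' @param abundance numeric matrix, samples in rows, metabolites in columns;
#'   rownames are sample ids, colnames are metabolite ids.
#' @param metadata data.frame with one row per sample and a `sample_id`
#'   column; rows are aligned to `abundance` on construction.
#' @return An object of class `ow_cohort`: a list with elements `abundance`,
#'   `metadata`, and `metabolite_ids`.
#' @export
cohort <- function(abundance, metadata) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance))) {
    stop("abundance must have sample ids as rownames")
  }
  if (is.null(colnames(abundance))) {
    stop("abundance must have metabolite ids as colnames")
  }
  if (anyDuplicated(rownames(abundance))) {
    dup <- rownames(abundance)[duplicated(rownames(abundance))][1]
    stop("duplicate sample_id: ", dup)
  }
  if (anyDuplicated(colnames(abundance))) {
    dup <- colnames(abundance)[duplicated(colnames(abundance))][1]
    stop("duplicate metabolite id: ", dup)
  }
  metadata <- as.data.frame(metadata)
  if (!"sample_id" %in% names(metadata)) {
    stop("metadata must contain a sample_id column")
  }
  if (anyDuplicated(metadata$sample_id)) {
    dup <- metadata$sample_id[duplicated(metadata$sample_id)][1]
    stop("duplicate sample_id: ", dup)
  }
  common <- intersect(rownames(abundance), metadata$sample_id)
  if (length(common) == 0) stop("no samples shared by abundance and metadata")
  lost <- setdiff(
    union(rownames(abundance), metadata$sample_id), common
  )
  if (length(lost) > 0) {
    warning(
      "dropping ", length(lost), " sample(s) absent from one table: ",
      paste(utils::head(lost, 5), collapse = ", ")
    )
  }
  abundance <- abundance[common, , drop = FALSE]
  metadata <- metadata[match(common, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  if ("stage" %in% names(metadata) && !all(is.na(metadata$stage))) {
    metadata$stage <- validate_stage(metadata$stage)
  }
  structure(
    list(
      abundance = abundance,
      metadata = metadata,
      metabolite_ids = colnames(abundance)
    ),
    class = "ow_cohort"
  )
}

stage_levels <- function() c("control", "osteopenia", "osteoporosis")

validate_stage <- function(stage) {
  stage <- as.character(stage)
  bad <- setdiff(stats::na.omit(unique(stage)), stage_levels())
  if (length(bad) > 0) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  }
  factor(stage, levels = stage_levels(), ordered = TRUE)
}

#' @export
print.ow_cohort <- function(x, ...) {
  cat(
    "ow_cohort:", nrow(x$abundance), "samples x",
    ncol(x$abundance), "metabolites\n"
  )
  if ("stage" %in% names(x$metadata) && !all(is.na(x$metadata$stage))) {
    print(table(x$metadata$stage))
  }
  n_miss <- sum(is.na(x$abundance))
  if (n_miss > 0) cat(n_miss, "missing cells\n")
  invisible(x)
}

#' @export
dim.ow_cohort <- function(x) dim(x$abundance)

#' Load a cohort from delimited abundance and metadata tables
#'
#' The abundance table holds one sample per row: the first column is the
#' sample id, all remaining columns are metabolite concentrations. The
#' metadata table is keyed by a `sample_id` column. Cells equal to one of
#' `missing_tokens` (after trimming whitespace) are read as missing; note
#' that below-detection-limit markers (`"<LOD"`) are treated as missing, not
#' as zero. Samples present in only one table are dropped with a warning.
#'
#' @param abundance_path,metadata_path paths to CSV or TSV files (delimiter
#'   sniffed from the first line).
#' @param missing_tokens character vector of cell values read as missing.
#' @return An [cohort()] object.
#' @export
load_cohort <- function(abundance_path, metadata_path,
                        missing_tokens = c("", "NA", "NaN", "<LOD")) {
  ab <- read_delim_sniff(abundance_path)
  md <- read_delim_sniff(metadata_path)
  if (!"sample_id" %in% names(md)) names(md)[1] <- "sample_id"
  ids <- as.character(ab[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id: ", ids[duplicated(ids)][1])
  }
  raw <- ab[, -1, drop = FALSE]
  num <- matrix(NA_real_, nrow(raw), ncol(raw),
    dimnames = list(ids, names(raw))
  )
  for (j in seq_along(raw)) {
    cell <- trimws(as.character(raw[[j]]))
    is_missing <- cell %in% missing_tokens | is.na(raw[[j]])
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_missing & is.na(val))
    if (length(bad) > 0) {
      stop(
        "non-numeric abundance cell at sample '", ids[bad[1]],
        "', metabolite '", names(raw)[j], "': \"", cell[bad[1]], "\""
      )
    }
    val[is_missing] <- NA_real_
    num[, j] <- val
  }
  cohort(num, md)
}

read_delim_sniff <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path,
    header = TRUE, sep = sep, stringsAsFactors = FALSE,
    check.names = FALSE, na.strings = NULL, colClasses = "character",
    quote = "\"", comment.char = ""
  )
}

#' Remove high-missingness metabolites and impute the remainder
#'
#' Metabolites whose fraction of missing cells is strictly greater than
#' `max_missing_fraction` (default 20%) are removed. Remaining missing cells
#' are imputed; the default imputes the per-metabolite median within each
#' gender stratum (falling back to the overall median when a stratum is
#' entirely missing), which is robust and leaves rank tests essentially
#' untouched. `half_min` imputes half of the observed minimum (a common
#' below-detection-limit convention); `none` leaves NAs in place.
#'
#' The removal report is attached as attribute `"removal_report"`: a
#' data.frame with `metabolite_id`, `missing_fraction` and `kept` (0/1),
#' retrievable via [removal_report()].
#'
#' @param x an `ow_cohort`.
#' @param max_missing_fraction proportion in `[0, 1)`.
#' @param impute one of `"median"`, `"half_min"`, `"none"`.
#' @param by_gender stratify median imputation by `metadata$gender` when the
#'   column is present.
#' @return Filtered (and imputed) `ow_cohort` with the removal report
#'   attached.
#' @export
filter_missing <- function(x, max_missing_fraction = 0.20,
                           impute = c("median", "half_min", "none"),
                           by_gender = TRUE) {
  stopifnot(inherits(x, "ow_cohort"))
  impute <- match.arg(impute)
  if (max_missing_fraction < 0 || max_missing_fraction >= 1) {
    stop("max_missing_fraction must lie in [0, 1)")
  }
  frac <- colMeans(is.na(x$abundance))
  keep <- frac <= max_missing_fraction
  if (!any(keep)) stop("all metabolites exceed the missingness threshold")
  report <- data.frame(
    metabolite_id = colnames(x$abundance),
    missing_fraction = unname(frac),
    kept = as.integer(keep),
    stringsAsFactors = FALSE
  )
  ab <- x$abundance[, keep, drop = FALSE]
  if (impute != "none" && anyNA(ab)) {
    strata <- if (by_gender && "gender" %in% names(x$metadata)) {
      as.character(x$metadata$gender)
    } else {
      rep("all", nrow(ab))
    }
    for (j in seq_len(ncol(ab))) {
      col <- ab[, j]
      nas <- which(is.na(col))
      if (length(nas) == 0) next
      fill <- if (impute == "half_min") {
        rep(min(col, na.rm = TRUE) / 2, length(nas))
      } else {
        overall <- stats::median(col, na.rm = TRUE)
        vapply(nas, function(i) {
          m <- stats::median(col[strata == strata[i]], na.rm = TRUE)
          if (is.na(m)) overall else m
        }, numeric(1))
      }
      col[nas] <- fill
      ab[, j] <- col
    }
  }
  out <- cohort(ab, x$metadata)
  attr(out, "removal_report") <- report
  out
}

#' @rdname filter_missing
#' @export
removal_report <- function(x) attr(x, "removal_report")

#' Bone-density T-scores
#'
#' T-score of a measured bone mineral density (BMD, g/cm^2) against a
#' young-adult reference population:
#' `(measured - young_adult_mean) / young_adult_sd`. The score is unit-free,
#' so a common rescaling of all three arguments leaves it unchanged.
#'
#' @param measured,young_mean,young_sd numeric vectors (recycled).
#' @return numeric vector of T-scores.
#' @export
t_score <- function(measured, young_mean, young_sd) {
  if (any(young_sd <= 0, na.rm = TRUE)) stop("young_sd must be positive")
  (measured - young_mean) / young_sd
}

#' Assign disease stage from per-site bone-density panels
#'
#' Each sample is measured at one or more skeletal sites (typically lumbar
#' spine L1-4, femoral neck, total hip). A sample is staged `osteoporosis`
#' when any site T-score falls below `osteoporosis_threshold` (-2.5),
#' `control` when every usable site is at or above `control_threshold`
#' (default -1.0, the WHO normal-bone-mass convention), and `osteopenia`
#' otherwise. Sites lacking a complete (measured, young mean, young SD)
#' triple are skipped with a warning; a sample with no usable site is an
#' error.
#'
#' @param panel data.frame with columns `sample_id`, `site`, `measured`,
#'   `young_mean`, `young_sd` (one row per sample x site).
#' @param osteoporosis_threshold,control_threshold stage cutpoints on the
#'   T-score scale; `osteoporosis_threshold < control_threshold` required.
#' @return ordered factor of stages, named by sample id (unique samples, in
#'   first-appearance order).
#' @export
assign_stage <- function(panel, osteoporosis_threshold = -2.5,
                         control_threshold = -1.0) {
  need <- c("sample_id", "site", "measured", "young_mean", "young_sd")
  if (!all(need %in% names(panel))) {
    stop("panel must have columns: ", paste(need, collapse = ", "))
  }
  if (osteoporosis_threshold >= control_threshold) {
    stop("osteoporosis_threshold must be below control_threshold")
  }
  ids <- unique(as.character(panel$sample_id))
  usable <- stats::complete.cases(
    panel[, c("measured", "young_mean", "young_sd")]
  ) & !is.na(panel$young_sd) & panel$young_sd > 0
  if (any(!usable)) {
    warning(sum(!usable), " site record(s) skipped: incomplete reference")
  }
  panel <- panel[usable, , drop = FALSE]
  ts <- t_score(panel$measured, panel$young_mean, panel$young_sd)
  stage <- vapply(ids, function(id) {
    s <- ts[panel$sample_id == id]
    if (length(s) == 0) stop("no usable BMD site for sample '", id, "'")
    if (any(s < osteoporosis_threshold)) {
      "osteoporosis"
    } else if (all(s >= control_threshold)) {
      "control"
    } else {
      "osteopenia"
    }
  }, character(1))
  stats::setNames(validate_stage(stage), ids)
}

# Abundance restricted to a stage; errors when the stage column is absent.
stage_abundance <- function(x, stage) {
  st <- cohort_stage(x)
  x$abundance[st == stage, , drop = FALSE]
}

cohort_stage <- function(x) {
  if (!"stage" %in% names(x$metadata) || all(is.na(x$metadata$stage))) {
    stop("cohort has no stage labels; run assign_stage() first")
  }
  validate_stage(x$metadata$stage)
}
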