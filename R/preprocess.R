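#' Remove decoy and contaminant rows
#'
#' Drops rows flagged reverse (search-engine decoys) or potential
#' contaminant before any quantitative analysis, preserving the order of
#' the remaining rows.
#'
#' @param mat an `lfq_matrix`.
#' @return the filtered `lfq_matrix` (possibly with zero rows).
#' @export
filter_decoys <- function(mat) {
  stopifnot(inherits(mat, "lfq_matrix"))
  keep <- !(mat$proteins$is_reverse | mat$proteins$is_contaminant)
  mat[keep]
}

#' Per-condition noise value for left-censored imputation
#'
#' The imputation value for one condition: a low percentile (default the
#' 1st) of all observed intensities across that condition's sample columns
#' and all proteins, computed with the linear-interpolation quantile
#' (`type = 7`).
#'
#' @param mat `lfq_matrix` on the linear scale.
#' @param design validated design table.
#' @param group condition group label.
#' @param sex optionally restrict the condition to one sex (the default
#'   analysis treats group x sex as the condition).
#' @param percentile quantile level in (0, 1); default 0.01.
#' @return a single numeric noise value.
#' @export
condition_noise_value <- function(mat, design, group, sex = NULL,
                                  percentile = 0.01) {
  stopifnot(inherits(mat, "lfq_matrix"), mat$scale == "linear")
  samples <- condition_samples(design, group, sex)
  if (!length(samples) || !all(samples %in% colnames(mat$values))) {
    stop("condition ", group, if (!is.null(sex)) paste0("/", sex),
         " has no matching sample columns", call. = FALSE)
  }
  x <- mat$values[, samples, drop = FALSE]
  x <- x[!is.na(x)]
  if (!length(x)) {
    stop("condition ", group, if (!is.null(sex)) paste0("/", sex),
         " has zero observed intensities; cannot compute a noise value",
         call. = FALSE)
  }
  stats::quantile(x, percentile, type = 7, names = FALSE)
}

#' Impute missing intensities with per-condition noise values
#'
#' Every missing cell in a condition is replaced by that condition's
#' [condition_noise_value()]; observed cells are untouched, so re-imputing
#' an already-imputed matrix changes nothing. The pre-imputation
#' missingness pattern is retained in the result's `raw_mask` for the
#' quantifiability and missingness gates.
#'
#' @param mat `lfq_matrix` on the linear scale.
#' @param design validated design table covering all sample columns.
#' @param condition_by `"group_sex"` (default: each group within each sex is
#'   its own condition, matching a sexes-analysed-separately workflow) or
#'   `"group"`.
#' @param percentile imputation percentile, default 0.01.
#' @return list with `matrix` (imputed `lfq_matrix`, no missing cells) and
#'   `report`: data.frame per condition (`condition`, `noise_linear`,
#'   `noise_log2`, `n_imputed`) with attribute `fraction_imputed`.
#' @export
impute_missing <- function(mat, design, condition_by = c("group_sex", "group"),
                           percentile = 0.01) {
  stopifnot(inherits(mat, "lfq_matrix"), mat$scale == "linear")
  condition_by <- match.arg(condition_by)
  if (!all(colnames(mat$values) %in% design$sample_id)) {
    stop("design does not cover all sample columns", call. = FALSE)
  }
  design <- design[match(colnames(mat$values), design$sample_id), ]

  conds <- if (condition_by == "group_sex") {
    unique(design[c("group", "sex")])
  } else {
    data.frame(group = unique(design$group))
  }
  values <- mat$values
  rep_rows <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    g <- conds$group[i]
    s <- if (condition_by == "group_sex") conds$sex[i] else NULL
    noise <- condition_noise_value(mat, design, g, s, percentile)
    samples <- condition_samples(design, g, s)
    block <- values[, samples, drop = FALSE]
    n_imp <- sum(is.na(block))
    block[is.na(block)] <- noise
    values[, samples] <- block
    rep_rows[[i]] <- data.frame(
      condition = paste(c(g, s), collapse = "_"),
      noise_linear = noise, noise_log2 = log2(noise), n_imputed = n_imp,
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rep_rows)
  attr(report, "fraction_imputed") <- sum(report$n_imputed) / length(values)
  list(matrix = lfq_matrix(values, mat$proteins, scale = "linear",
                           raw_mask = mat$raw_mask),
       report = report)
}

#' Quantifiability mask for a pairwise comparison
#'
#' A protein is quantifiable for a two-condition comparison iff it has a
#' complete set of observed (pre-imputation) intensities in all replicates
#' of at least one of the two conditions, and at least two unique + razor
#' peptides. When a protein fails, a single reason is recorded
#' (`insufficient_replicates` takes precedence over `too_few_peptides` when
#' both fail).
#'
#' @param raw_mask logical proteins x samples matrix of pre-imputation
#'   missingness (TRUE = missing), e.g. the `raw_mask` of an `lfq_matrix`.
#' @param peptide_counts integer vector, one per protein row.
#' @param design validated design table.
#' @param condition_a,condition_b group labels of the comparison.
#' @param sex optionally restrict both conditions to one sex.
#' @return data.frame `protein_id` (rownames of `raw_mask`), `quantifiable`,
#'   `reason` (`NA`, `"insufficient_replicates"` or `"too_few_peptides"`).
#' @export
quantifiability_mask <- function(raw_mask, peptide_counts, design,
                                 condition_a, condition_b, sex = NULL) {
  for (cond in c(condition_a, condition_b)) {
    samples <- condition_samples(design, cond, sex)
    if (!length(samples)) {
      stop("comparison condition ", cond,
           " absent from design", call. = FALSE)
    }
    if (!all(samples %in% colnames(raw_mask))) {
      stop("samples of condition ", cond, " missing from the matrix",
           call. = FALSE)
    }
  }
  sa <- condition_samples(design, condition_a, sex)
  sb <- condition_samples(design, condition_b, sex)
  complete_a <- rowSums(raw_mask[, sa, drop = FALSE]) == 0
  complete_b <- rowSums(raw_mask[, sb, drop = FALSE]) == 0
  replicate_ok <- complete_a | complete_b
  peptide_ok <- peptide_counts >= 2
  quantifiable <- replicate_ok & peptide_ok
  reason <- rep(NA_character_, nrow(raw_mask))
  reason[!replicate_ok] <- "insufficient_replicates"
  reason[replicate_ok & !peptide_ok] <- "too_few_peptides"
  data.frame(protein_id = rownames(raw_mask),
             quantifiable = quantifiable,
             reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}
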