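#' Configuration for the covariate correlation screen
#'
#' @param alpha two-sided significance level for the Pearson gate
#'   (default 0.01).
#' @param fold_gate minimum absolute extreme-group ratio; the gate passes
#'   when `max(ratio, 1/ratio) > fold_gate` so both directions of change
#'   are admitted (default 2).
#' @param max_missing maximum pre-imputation missing samples per protein
#'   within one sex; proteins missing in more samples are excluded
#'   (default 5).
#' @param extreme_groups character pair `(high, low)` of condition labels
#'   whose imputed-mean ratio feeds the fold gate (default GL40 / GL00, the
#'   extremes of the ascorbate dose range).
#' @param scale scale on which Pearson r is computed over imputed values:
#'   `"log2"` (default) or `"linear"`.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(alpha = 0.01, fold_gate = 2, max_missing = 5,
                          extreme_groups = c(high = "GL40", low = "GL00"),
                          scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (fold_gate < 1) stop("fold_gate must be >= 1", call. = FALSE)
  if (length(extreme_groups) != 2) {
    stop("extreme_groups must name a (high, low) pair", call. = FALSE)
  }
  structure(list(alpha = alpha, fold_gate = fold_gate,
                 max_missing = max_missing,
                 extreme_groups = stats::setNames(extreme_groups,
                                                  c("high", "low")),
                 scale = scale),
            class = "screen_config")
}

#' Critical Pearson correlation at a given sample size and level
#'
#' Magnitude a sample correlation must exceed to reject zero correlation:
#' `t* / sqrt(t*^2 + n - 2)` with `t*` the two-sided t critical value at
#' `alpha` with `n - 2` df. For n = 18 and alpha = 0.01 this is 0.5897 to
#' four decimals.
#'
#' @param n number of paired samples (>= 3).
#' @param alpha two-sided level in (0, 1).
#' @return the critical |r|.
#' @export
critical_r <- function(n, alpha) {
  if (n < 3) stop("critical_r needs n >= 3", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  tstar <- stats::qt(1 - alpha / 2, df = n - 2)
  tstar / sqrt(tstar^2 + n - 2)
}

#' Pearson correlation of one intensity row with the covariate
#'
#' Computed over imputed values, so every sample contributes
#' (`n_used = n`); high-missingness proteins are handled by the
#' `max_missing` gate, not by pairwise deletion. If either vector has zero
#' variance, r is undefined and returned as NA with a reason attribute.
#'
#' @param intensity numeric vector (imputed; no NA).
#' @param covariate numeric vector, same length (>= 3).
#' @return list `r`, `n_used`, `reason` (NA or `"zero_variance"`).
#' @export
pearson_with_missing <- function(intensity, covariate) {
  if (length(intensity) != length(covariate) || length(intensity) < 3) {
    stop("need >= 3 paired values", call. = FALSE)
  }
  if (anyNA(intensity) || anyNA(covariate)) {
    stop("inputs must be imputed (no NA); missingness is handled by the ",
         "max_missing gate", call. = FALSE)
  }
  if (stats::sd(intensity) == 0 || stats::sd(covariate) == 0) {
    return(list(r = NA_real_, n_used = length(intensity),
                reason = "zero_variance"))
  }
  list(r = stats::cor(intensity, covariate), n_used = length(intensity),
       reason = NA_character_)
}

#' Screen one sex's proteins for covariate correlation
#'
#' For each protein: Pearson r of (log2 by default) imputed intensity
#' against the per-animal covariate over the sex's samples, then three
#' gates: (1) `passed_missing` — at most `max_missing` pre-imputation
#' missing samples; (2) `passed_fold` — absolute imputed-mean ratio between
#' the extreme groups exceeds `fold_gate` in either direction; (3)
#' `passed_r` — `|r|` exceeds [critical_r()] at the sex's sample count.
#' Direction (positive/negative) is set only when all three gates pass; the
#' gates are independent of application order.
#'
#' @param imputed imputed `lfq_matrix` (linear scale, pre-imputation
#'   missingness in `raw_mask`).
#' @param design validated design table.
#' @param sex which sex's samples to screen (`NULL` = all samples).
#' @param config a [screen_config()].
#' @return data.frame per protein: `protein_id`, `r`, `n_used`,
#'   `passed_r`, `passed_fold`, `passed_missing`, `direction`
#'   (`positive`/`negative`/`none`).
#' @export
correlation_screen <- function(imputed, design, sex = NULL,
                               config = screen_config()) {
  stopifnot(inherits(imputed, "lfq_matrix"), inherits(config, "screen_config"))
  if (imputed$scale != "linear") {
    stop("correlation_screen expects the imputed linear-scale matrix",
         call. = FALSE)
  }
  for (g in config$extreme_groups) {
    if (!length(condition_samples(design, g, sex))) {
      stop("extreme group ", g, " absent from design", call. = FALSE)
    }
  }
  keep <- if (is.null(sex)) rep(TRUE, nrow(design)) else design$sex == sex
  d <- design[keep, ]
  samples <- d$sample_id
  if (!all(samples %in% colnames(imputed$values))) {
    stop("design samples missing from the matrix", call. = FALSE)
  }
  vals <- imputed$values[, samples, drop = FALSE]
  if (anyNA(vals)) stop("matrix has missing cells; impute first", call. = FALSE)
  x <- if (config$scale == "log2") log2(vals) else vals
  n <- length(samples)
  r_crit <- critical_r(n, config$alpha)

  cov <- d$covariate
  r <- vapply(seq_len(nrow(x)), function(i) {
    pearson_with_missing(x[i, ], cov)$r
  }, 0)

  n_missing <- rowSums(imputed$raw_mask[, samples, drop = FALSE])
  hi <- condition_samples(d, config$extreme_groups[["high"]], sex)
  lo <- condition_samples(d, config$extreme_groups[["low"]], sex)
  ratio <- rowMeans(vals[, hi, drop = FALSE]) /
    rowMeans(vals[, lo, drop = FALSE])

  rec <- data.frame(protein_id = imputed$proteins$protein_id,
                    r = r, n_used = n,
                    passed_r = !is.na(r) & abs(r) > r_crit,
                    passed_fold = pmax(ratio, 1 / ratio) > config$fold_gate,
                    passed_missing = n_missing <= config$max_missing,
                    stringsAsFactors = FALSE, row.names = NULL)
  all_pass <- rec$passed_r & rec$passed_fold & rec$passed_missing
  rec$direction <- ifelse(all_pass & r > 0, "positive",
                          ifelse(all_pass & r < 0, "negative", "none"))
  rec
}

#' Per-sex correlated-protein lists and their cross-sex intersections
#'
#' @param records_by_sex named list (e.g. `F`, `M`) of
#'   [correlation_screen()] results.
#' @return list: `positive` and `negative` (named lists of protein ids per
#'   sex), `positive_common` and `negative_common` (ids shared by every
#'   sex), `sizes` (named integer vector).
#' @export
screen_and_intersect <- function(records_by_sex) {
  stopifnot(length(names(records_by_sex)) == length(records_by_sex))
  pick <- function(rec, dir) sort(rec$protein_id[rec$direction == dir])
  positive <- lapply(records_by_sex, pick, "positive")
  negative <- lapply(records_by_sex, pick, "negative")
  pos_common <- Reduce(intersect, positive)
  neg_common <- Reduce(intersect, negative)
  sizes <- c(stats::setNames(vapply(positive, length, 0L),
                             paste0("positive_", names(positive))),
             stats::setNames(vapply(negative, length, 0L),
                             paste0("negative_", names(negative))),
             positive_common = length(pos_common),
             negative_common = length(neg_common))
  list(positive = positive, negative = negative,
       positive_common = pos_common, negative_common = neg_common,
       sizes = sizes)
}
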