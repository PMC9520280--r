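#' Resolve a two-condition comparison against the design
#'
#' @param design validated design table.
#' @param condition_a,condition_b group labels.
#' @param sex optionally restrict to one sex (the default workflow analyses
#'   females and males separately).
#' @return list of class `comparison_spec` with the condition labels and the
#'   resolved, disjoint sample-id sets.
#' @export
comparison_spec <- function(design, condition_a, condition_b, sex = NULL) {
  sa <- condition_samples(design, condition_a, sex)
  sb <- condition_samples(design, condition_b, sex)
  if (!length(sa)) stop("condition ", condition_a, " absent from design",
                        call. = FALSE)
  if (!length(sb)) stop("condition ", condition_b, " absent from design",
                        call. = FALSE)
  if (length(intersect(sa, sb))) {
    stop("comparison conditions share samples", call. = FALSE)
  }
  structure(list(condition_a = condition_a, condition_b = condition_b,
                 sex = sex, samples_a = sa, samples_b = sb),
            class = "comparison_spec")
}

#' Per-protein group statistics for a comparison
#'
#' Means and ratio are on the (imputed) linear scale, as a ratio of LFQ
#' intensity means; the log2 fold change and the pooled variance are on the
#' log2 scale, where variance modelling is standard. Note `ratio` is a ratio
#' of arithmetic means and is not `2^log2fc` in general.
#'
#' @param mat imputed `lfq_matrix` on the linear scale (no missing cells).
#' @param spec a [comparison_spec()].
#' @return data.frame per protein: `protein_id`, `mean_a`, `mean_b`,
#'   `ratio`, `log2fc`, `s_g_sq` (pooled within-group variance of log2
#'   values), and attribute `d_g` (= n_a + n_b - 2 residual df).
#' @export
group_stats <- function(mat, spec) {
  stopifnot(inherits(mat, "lfq_matrix"), inherits(spec, "comparison_spec"))
  if (mat$scale != "linear") stop("group_stats expects the linear scale",
                                  call. = FALSE)
  if (anyNA(mat$values)) stop("matrix has missing cells; impute first",
                              call. = FALSE)
  a <- mat$values[, spec$samples_a, drop = FALSE]
  b <- mat$values[, spec$samples_b, drop = FALSE]
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  if (any(mean_b == 0)) {
    stop("zero group mean on the linear scale; imputation should have ",
         "replaced missing cells by a positive noise value", call. = FALSE)
  }
  la <- log2(a); lb <- log2(b)
  n_a <- ncol(a); n_b <- ncol(b)
  var_a <- apply(la, 1, stats::var)
  var_b <- apply(lb, 1, stats::var)
  d_g <- n_a + n_b - 2L
  out <- data.frame(protein_id = mat$proteins$protein_id,
                    mean_a = mean_a, mean_b = mean_b,
                    ratio = mean_a / mean_b,
                    log2fc = rowMeans(la) - rowMeans(lb),
                    s_g_sq = ((n_a - 1) * var_a + (n_b - 1) * var_b) / d_g,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d_g") <- d_g
  attr(out, "n_a") <- n_a
  attr(out, "n_b") <- n_b
  out
}

#' Robust Z-scores of per-comparison log2 ratios
#'
#' Standardises the vector of log2 fold changes by its median and its
#' MAD (scaled by 1.4826 for normal consistency), so that the +/-1.96 call
#' threshold keeps its nominal meaning even when many proteins shift.
#'
#' @param log2fc numeric vector over the quantifiable proteins of one
#'   comparison (length >= 10).
#' @return numeric vector of Z-scores.
#' @export
log_ratio_zscores <- function(log2fc) {
  if (length(log2fc) < 10) {
    stop("need >= 10 quantifiable proteins to standardise log2 ratios",
         call. = FALSE)
  }
  center <- stats::median(log2fc)
  scale <- stats::mad(log2fc)  # constant 1.4826
  if (scale == 0) {
    stop("degenerate comparison: MAD of log2 ratios is zero", call. = FALSE)
  }
  (log2fc - center) / scale
}

# solve trigamma(y) = x by Newton iteration (monotone, convex target)
trigamma_inverse <- function(x) {
  stopifnot(length(x) == 1, is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Fit empirical-Bayes variance-moderation hyperparameters
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_sq`
#' of the scaled inverse-chi-square prior on per-protein variances by
#' moment matching on the log variances: with
#' `z_g = log(s_g_sq) - digamma(d_g/2) + log(d_g/2)`, solves
#' `trigamma(d0/2) = var(z) - trigamma(d_g/2)` by Newton root-finding on
#' the trigamma inverse, then recovers `s0_sq` from the mean relation.
#' When the observed dispersion of log variances does not exceed its
#' sampling expectation, `d0` is infinite and every moderated variance
#' equals `s0_sq`.
#'
#' Zero variances (possible when imputation makes a group constant) are
#' excluded from the moment fit but still receive a moderated variance
#' through the prior.
#'
#' @param s_g_sq per-protein residual variances (log2 scale).
#' @param d_g residual degrees of freedom shared by all proteins.
#' @return list of class `ebayes_params`: `d0`, `s0_sq`, `d_g`,
#'   `n_used` (variances entering the fit).
#' @export
fit_ebayes <- function(s_g_sq, d_g) {
  ok <- is.finite(s_g_sq) & s_g_sq > 0
  if (sum(ok) < 10) {
    stop("need >= 10 positive finite variances to fit the prior",
         call. = FALSE)
  }
  z <- log(s_g_sq[ok]) - digamma(d_g / 2) + log(d_g / 2)
  evar <- stats::var(z) - trigamma(d_g / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(z) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion beyond sampling noise: infinite prior df and the
    # geometric-moment estimate of the common variance
    d0 <- Inf
    s0_sq <- exp(mean(log(s_g_sq[ok])))
  }
  structure(list(d0 = d0, s0_sq = s0_sq, d_g = d_g, n_used = sum(ok)),
            class = "ebayes_params")
}

#' Moderated (shrunken) per-protein variances
#'
#' `s2_tilde = (d0 * s0_sq + d_g * s_g_sq) / (d0 + d_g)`, a convex
#' combination lying between the prior and the observed variance; equals
#' `s0_sq` when `d0` is infinite and `s_g_sq` when `d0 = 0`.
#'
#' @param s_g_sq per-protein residual variances.
#' @param params an `ebayes_params` fit, or a list with `d0`, `s0_sq`.
#' @return numeric vector of moderated variances.
#' @export
moderated_variance <- function(s_g_sq, params) {
  if (is.infinite(params$d0)) {
    rep(params$s0_sq, length(s_g_sq))
  } else {
    (params$d0 * params$s0_sq + params$d_g * s_g_sq) /
      (params$d0 + params$d_g)
  }
}

#' Moderated t-statistic and two-sided p-value
#'
#' `t = log2fc / sqrt(s2_tilde * (1/n_a + 1/n_b))`, referred to a t
#' distribution with `d0 + d_g` degrees of freedom (standard normal when
#' `d0` is infinite). With `d0 = 0` (moderation off, `s2_tilde = s_g_sq`)
#' this is the ordinary pooled two-sample t-statistic.
#'
#' @param log2fc per-protein log2 fold changes.
#' @param s2_tilde moderated variances from [moderated_variance()].
#' @param n_a,n_b group sizes.
#' @param d0 prior df; `Inf` allowed.
#' @param d_g residual df.
#' @return data.frame `t_mod`, `p`.
#' @export
moderated_t <- function(log2fc, s2_tilde, n_a, n_b, d0, d_g) {
  se <- sqrt(s2_tilde * (1 / n_a + 1 / n_b))
  t_mod <- log2fc / se
  df <- d0 + d_g
  p <- 2 * stats::pt(-abs(t_mod), df = df)
  data.frame(t_mod = t_mod, p = p)
}

#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at
#' 1, returned in the input order. Delegates to [stats::p.adjust()] after
#' validating the input range.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no NA", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Dual-criterion significance call
#'
#' A protein is called over-expressed (`up`) iff `q < q_threshold` AND
#' `z > z_threshold`, under-expressed (`down`) iff `q < q_threshold` AND
#' `z < -z_threshold`, otherwise `ns`. Either criterion alone is
#' insufficient. Proteins failing the quantifiability mask are
#' `not_quantifiable`.
#'
#' @param q,zscore per-protein vectors (NA allowed for non-quantifiable
#'   rows).
#' @param quantifiable logical vector.
#' @param q_threshold q-value cutoff, default 0.05.
#' @param z_threshold Z cutoff, default `qnorm(0.975)` = 1.96 (two-sided
#'   normal at 5%).
#' @return character vector in `{up, down, ns, not_quantifiable}`.
#' @export
call_proteins <- function(q, zscore, quantifiable = rep(TRUE, length(q)),
                          q_threshold = 0.05,
                          z_threshold = stats::qnorm(0.975)) {
  call <- rep("ns", length(q))
  call[quantifiable & !is.na(q) & q < q_threshold & zscore > z_threshold] <- "up"
  call[quantifiable & !is.na(q) & q < q_threshold & zscore < -z_threshold] <- "down"
  call[!quantifiable] <- "not_quantifiable"
  call
}

#' Run one pairwise differential-abundance comparison
#'
#' Applies the quantifiability mask (complete replicates in at least one
#' condition, >= 2 peptides), computes linear-scale means and ratio, log2
#' fold change, robust Z-score, empirical-Bayes moderated t and BH q-value
#' over the quantifiable proteins, and the dual-criterion call. Statistics
#' of non-quantifiable proteins are absent (NA).
#'
#' @param imputed imputed `lfq_matrix` (linear scale, `raw_mask` holding
#'   pre-imputation missingness).
#' @param design validated design table.
#' @param condition_a,condition_b group labels.
#' @param sex optionally restrict to one sex.
#' @param q_threshold,z_threshold call thresholds, see [call_proteins()].
#' @return data.frame (one row per protein): `protein_id`, `comparison`,
#'   `sex`, `mean_a`, `mean_b`, `ratio`, `log2fc`, `zscore`, `t_mod`, `p`,
#'   `q`, `call`.
#' @export
run_comparison <- function(imputed, design, condition_a, condition_b,
                           sex = NULL, q_threshold = 0.05,
                           z_threshold = stats::qnorm(0.975)) {
  spec <- comparison_spec(design, condition_a, condition_b, sex)
  mask <- quantifiability_mask(imputed$raw_mask, imputed$proteins$peptide_count,
                               design, condition_a, condition_b, sex)
  gs <- group_stats(imputed, spec)
  n <- nrow(gs)
  out <- data.frame(protein_id = gs$protein_id,
                    comparison = paste0(condition_a, "_vs_", condition_b),
                    sex = if (is.null(sex)) NA_character_ else sex,
                    mean_a = NA_real_, mean_b = NA_real_, ratio = NA_real_,
                    log2fc = NA_real_, zscore = NA_real_, t_mod = NA_real_,
                    p = NA_real_, q = NA_real_, call = NA_character_,
                    stringsAsFactors = FALSE, row.names = NULL)
  qf <- mask$quantifiable
  out[qf, c("mean_a", "mean_b", "ratio", "log2fc")] <-
    gs[qf, c("mean_a", "mean_b", "ratio", "log2fc")]
  if (any(qf)) {
    z <- log_ratio_zscores(gs$log2fc[qf])
    eb <- fit_ebayes(gs$s_g_sq[qf], attr(gs, "d_g"))
    s2t <- moderated_variance(gs$s_g_sq[qf], eb)
    mt <- moderated_t(gs$log2fc[qf], s2t, attr(gs, "n_a"), attr(gs, "n_b"),
                      eb$d0, eb$d_g)
    out$zscore[qf] <- z
    out$t_mod[qf] <- mt$t_mod
    out$p[qf] <- mt$p
    out$q[qf] <- bh_adjust(mt$p)
  }
  out$call <- call_proteins(out$q, out$zscore, qf, q_threshold, z_threshold)
  out
}

#' Aggregate calls across comparisons and sexes
#'
#' Union per sex = proteins called up or down in at least one of that sex's
#' comparisons; intersection = proteins in the union of every sex.
#'
#' @param records a data.frame of [run_comparison()] rows (stacked) with a
#'   `sex` column, or a list of such data.frames.
#' @return list: `union` (named list of protein-id vectors per sex),
#'   `intersection` (protein ids significant in every sex), `sizes`
#'   (named integer vector).
#' @export
aggregate_calls <- function(records) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, records)
  }
  sexes <- unique(records$sex)
  sig <- records$call %in% c("up", "down")
  union <- lapply(stats::setNames(sexes, sexes), function(s) {
    sort(unique(records$protein_id[sig & records$sex == s]))
  })
  intersection <- if (length(union)) Reduce(intersect, union) else character(0)
  sizes <- c(vapply(union, length, 0L), intersection = length(intersection))
  list(union = union, intersection = intersection, sizes = sizes)
}
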