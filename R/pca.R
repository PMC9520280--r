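#' PCA of the imputed intensity matrix
#'
#' Samples are observations, proteins are features. The matrix is centered
#' per protein and optionally unit-scaled; scores are the projections of
#' samples onto the top-k right singular directions. The component sign is
#' fixed by making each loading's largest-magnitude entry positive, so
#' results are reproducible across platforms.
#'
#' @param mat imputed `lfq_matrix` on the log2 scale (no missing cells).
#' @param center center each protein; default TRUE.
#' @param unit_scale scale each protein to unit variance; constant proteins
#'   are dropped with a warning when TRUE. Default TRUE.
#' @param k number of components (default 2).
#' @return list of class `lfq_pca`: `scores` (samples x k), `loadings`
#'   (proteins x k, orthonormal columns), `explained_variance` (fractions
#'   of total variance, non-increasing, summing to <= 1), `dropped`
#'   (ids of constant proteins removed).
#' @export
lfq_pca <- function(mat, center = TRUE, unit_scale = TRUE, k = 2) {
  stopifnot(inherits(mat, "lfq_matrix"))
  if (mat$scale != "log2") {
    stop("lfq_pca expects the log2-scale matrix; see log2_transform()",
         call. = FALSE)
  }
  if (anyNA(mat$values)) {
    stop("matrix has missing cells; impute first", call. = FALSE)
  }
  x <- t(mat$values)  # samples x proteins
  dropped <- character(0)
  if (unit_scale) {
    const <- apply(x, 2, stats::sd) == 0
    if (any(const)) {
      dropped <- colnames(x)[const]
      warning(sum(const), " constant protein(s) dropped before unit scaling")
      x <- x[, !const, drop = FALSE]
    }
  }
  if (k > min(dim(x))) {
    stop("k must be <= min(samples, proteins)", call. = FALSE)
  }
  fit <- stats::prcomp(x, center = center, scale. = unit_scale)
  scores <- fit$x[, seq_len(k), drop = FALSE]
  loadings <- fit$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- fit$sdev^2
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = (ev / sum(ev))[seq_len(k)],
                 dropped = dropped),
            class = "lfq_pca")
}

#' @export
print.lfq_pca <- function(x, ...) {
  cat(sprintf("<lfq_pca> %d samples, %d components; explained variance: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance),
                    collapse = ", ")))
  invisible(x)
}
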