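#' LFQ intensity matrix container
#'
#' Bundles a proteins x samples intensity matrix (with `NA` marking missing
#' cells), per-protein metadata, and a scale tag. All pipeline stages declare
#' the scale they require; `"linear"` holds raw LFQ intensities, `"log2"`
#' their log2 transform.
#'
#' @param values numeric matrix, proteins in rows, samples in columns;
#'   `NA` encodes a missing (unquantified) cell. Row and column names are
#'   taken from `proteins$protein_id` and the design if absent.
#' @param proteins data.frame of per-protein metadata with at least
#'   `protein_id`, `gene_name`, `peptide_count`, `is_reverse`,
#'   `is_contaminant`; one row per matrix row.
#' @param scale `"linear"` or `"log2"`.
#' @param raw_mask optional logical matrix of the pre-imputation missingness
#'   pattern (TRUE = was missing). Stored so that gates that must see the
#'   original missingness (quantifiability, the >5-missing exclusion) survive
#'   imputation.
#'
#' @return An object of class `lfq_matrix`: a list with elements `values`,
#'   `proteins`, `scale`, `raw_mask`.
#' @export
lfq_matrix <- function(values, proteins, scale = c("linear", "log2"),
                       raw_mask = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != nrow(proteins)) {
    stop("`values` has ", nrow(values), " rows but `proteins` has ",
         nrow(proteins), call. = FALSE)
  }
  req <- c("protein_id", "gene_name", "peptide_count", "is_reverse",
           "is_contaminant")
  miss <- setdiff(req, names(proteins))
  if (length(miss)) {
    stop("`proteins` lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(proteins$protein_id)) {
    stop("duplicate protein_id in `proteins`", call. = FALSE)
  }
  if (scale == "linear" && any(values < 0, na.rm = TRUE)) {
    stop("linear-scale intensities must be >= 0", call. = FALSE)
  }
  rownames(values) <- proteins$protein_id
  if (is.null(raw_mask)) raw_mask <- is.na(values)
  stopifnot(identical(dim(raw_mask), dim(values)))
  dimnames(raw_mask) <- dimnames(values)
  structure(list(values = values, proteins = as.data.frame(proteins),
                 scale = scale, raw_mask = raw_mask),
            class = "lfq_matrix")
}

#' @export
print.lfq_matrix <- function(x, ...) {
  cat(sprintf("<lfq_matrix> %d proteins x %d samples [%s scale], %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.lfq_matrix <- function(x) dim(x$values)

#' Subset an lfq_matrix by protein rows
#' @param x an `lfq_matrix`.
#' @param i row index (logical, integer or protein_id character).
#' @param ... unused.
#' @return the subsetted `lfq_matrix`.
#' @export
`[.lfq_matrix` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$proteins$protein_id)
  lfq_matrix(x$values[i, , drop = FALSE],
             x$proteins[i, , drop = FALSE],
             scale = x$scale,
             raw_mask = x$raw_mask[i, , drop = FALSE])
}

#' Log2-transform a linear-scale lfq_matrix
#'
#' Cells equal to zero cannot occur on the linear scale after imputation
#' (the noise value is strictly positive); an error is raised if any are
#' present among observed cells.
#'
#' @param x an `lfq_matrix` on the linear scale.
#' @return the matrix on the log2 scale (raw_mask carried over unchanged).
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (x$scale != "linear") stop("matrix is already on the log2 scale", call. = FALSE)
  if (any(x$values == 0, na.rm = TRUE)) {
    stop("observed zero intensities present; zeros must be ingested as missing",
         call. = FALSE)
  }
  lfq_matrix(log2(x$values), x$proteins, scale = "log2", raw_mask = x$raw_mask)
}

# samples (column names) belonging to one condition; condition is group,
# optionally within one sex
condition_samples <- function(design, group, sex = NULL) {
  keep <- design$group == group
  if (!is.null(sex)) keep <- keep & design$sex == sex
  design$sample_id[keep]
}
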