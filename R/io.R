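#' Column-name conventions for MaxQuant-style protein tables
#'
#' Maps the logical fields the pipeline needs onto the column names of the
#' tab-delimited protein-group table. Defaults follow the MaxQuant
#' proteinGroups.txt dialect; per-sample intensity columns are recognised by
#' prefix, with the remainder of the name taken as the sample id.
#'
#' @param id protein accession column (semicolon-separated groups allowed;
#'   the first accession is the representative).
#' @param gene gene-name column (optional in the file).
#' @param peptides unique + razor peptide-count column.
#' @param reverse,contaminant marker columns using the "+" convention.
#' @param intensity_prefix prefix of per-sample LFQ intensity columns.
#' @return a named list of class `mq_column_map`.
#' @export
mq_column_map <- function(id = "Majority protein IDs",
                          gene = "Gene names",
                          peptides = "Razor + unique peptides",
                          reverse = "Reverse",
                          contaminant = "Potential contaminant",
                          intensity_prefix = "LFQ intensity ") {
  structure(list(id = id, gene = gene, peptides = peptides,
                 reverse = reverse, contaminant = contaminant,
                 intensity_prefix = intensity_prefix),
            class = "mq_column_map")
}

#' Read a MaxQuant-style protein-group table
#'
#' Intensity cells that are empty or exactly 0 become missing (MaxQuant
#' writes 0 for unquantified LFQ cells). Reverse / contaminant flags are
#' parsed from their "+" marker columns. Row order is preserved. For
#' semicolon-separated accession groups the first accession is used as the
#' protein id; the full group is kept in the `protein_group` metadata
#' column.
#'
#' @param path tab-delimited file with a header row.
#' @param column_map an [mq_column_map()].
#' @return an [lfq_matrix()] on the linear scale.
#' @export
read_protein_table <- function(path, column_map = mq_column_map()) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           colClasses = "character")
  mandatory <- c(id = column_map$id, peptides = column_map$peptides,
                 reverse = column_map$reverse,
                 contaminant = column_map$contaminant)
  absent <- mandatory[!mandatory %in% names(raw)]
  int_cols <- names(raw)[startsWith(names(raw), column_map$intensity_prefix)]
  if (length(absent) || !length(int_cols)) {
    msg <- character(0)
    if (length(absent)) msg <- paste0("column(s) not found: ",
                                      paste(sQuote(absent), collapse = ", "))
    if (!length(int_cols))
      msg <- c(msg, paste0("no columns with prefix ",
                           sQuote(column_map$intensity_prefix)))
    stop("protein table format error: ", paste(msg, collapse = "; "),
         call. = FALSE)
  }
  sample_ids <- substring(int_cols, nchar(column_map$intensity_prefix) + 1L)

  values <- matrix(NA_real_, nrow(raw), length(int_cols),
                   dimnames = list(NULL, sample_ids))
  for (j in seq_along(int_cols)) {
    cell <- trimws(raw[[int_cols[j]]])
    blank <- is.na(cell) | cell == "" | cell == "NA" | cell == "NaN"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!blank & is.na(num))
    if (length(bad)) {
      stop(sprintf("parse error: non-numeric intensity %s at row %d, column '%s'",
                   sQuote(cell[bad[1]]), bad[1], int_cols[j]), call. = FALSE)
    }
    num[blank | num == 0] <- NA_real_   # 0 => missing on ingest
    values[, j] <- num
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("parse error: negative intensity value in protein table", call. = FALSE)
  }

  pep <- suppressWarnings(as.integer(raw[[column_map$peptides]]))
  if (anyNA(pep)) {
    stop("parse error: non-integer peptide count at row ",
         which(is.na(pep))[1], call. = FALSE)
  }
  plus <- function(col) {
    if (!col %in% names(raw)) return(rep(FALSE, nrow(raw)))
    trimws(raw[[col]]) == "+"
  }
  group <- raw[[column_map$id]]
  proteins <- data.frame(
    protein_id = vapply(strsplit(group, ";", fixed = TRUE), `[`, "", 1L),
    protein_group = group,
    gene_name = if (column_map$gene %in% names(raw)) raw[[column_map$gene]]
                else "",
    peptide_count = pep,
    is_reverse = plus(column_map$reverse),
    is_contaminant = plus(column_map$contaminant),
    stringsAsFactors = FALSE)
  lfq_matrix(values, proteins, scale = "linear")
}

#' Write an lfq_matrix as a MaxQuant-style protein table
#'
#' Inverse of [read_protein_table()]: missing cells are written as 0, flags
#' as "+"/"" markers.
#'
#' @param mat an `lfq_matrix` on the linear scale.
#' @param path output path.
#' @param column_map an [mq_column_map()].
#' @return invisibly, `path`.
#' @export
write_protein_table <- function(mat, path, column_map = mq_column_map()) {
  stopifnot(inherits(mat, "lfq_matrix"), mat$scale == "linear")
  vals <- mat$values
  vals[is.na(vals)] <- 0
  out <- data.frame(
    id = if ("protein_group" %in% names(mat$proteins))
           mat$proteins$protein_group else mat$proteins$protein_id,
    gene = mat$proteins$gene_name,
    pep = mat$proteins$peptide_count,
    rev = ifelse(mat$proteins$is_reverse, "+", ""),
    con = ifelse(mat$proteins$is_contaminant, "+", ""),
    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c(column_map$id, column_map$gene, column_map$peptides,
                  column_map$reverse, column_map$contaminant)
  intensities <- as.data.frame(vals, check.names = FALSE)
  names(intensities) <- paste0(column_map$intensity_prefix, colnames(vals))
  utils::write.table(cbind(out, intensities), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a study design table
#'
#' @param path TSV with columns `sample_id`, `group`, `sex` (F/M) and
#'   `covariate` (non-negative; e.g. ng ascorbate per mg tissue).
#' @return validated design data.frame.
#' @export
read_design <- function(path) {
  # colClasses: a sex column of all "F" must not be read as logical FALSE
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#", colClasses = "character")
  validate_design(d)
}

#' Validate a design data.frame
#'
#' Checks the contract assumed throughout the pipeline: mandatory columns,
#' unique sample ids, known sex codes, and a non-negative numeric covariate.
#'
#' @param design data.frame to validate.
#' @return the design, invisibly usable downstream.
#' @export
validate_design <- function(design) {
  need <- c("sample_id", "group", "sex", "covariate")
  miss <- setdiff(need, names(design))
  if (length(miss)) {
    stop("design validation error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dup <- design$sample_id[duplicated(design$sample_id)]
  if (length(dup)) {
    stop("design validation error: duplicate sample_id ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (!all(design$sex %in% c("F", "M"))) {
    stop("design validation error: unknown sex code ",
         paste(setdiff(unique(design$sex), c("F", "M")), collapse = ", "),
         call. = FALSE)
  }
  design$covariate <- as.numeric(design$covariate)
  if (anyNA(design$covariate) || any(design$covariate < 0)) {
    stop("design validation error: covariate must be numeric and >= 0",
         call. = FALSE)
  }
  design
}

#' Write a results table with a provenance header
#'
#' Writes any per-protein results data.frame (differential records,
#' correlation records, report tables) as TSV with full-precision floats,
#' preceded by `#`-prefixed provenance comment lines. Re-readable with
#' [read_results()].
#'
#' @param records data.frame; an empty one yields a header-only file.
#' @param path output path.
#' @param provenance optional named character vector written as
#'   `# name: value` lines.
#' @return invisibly, `path`.
#' @export
write_results <- function(records, path, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(provenance)) {
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  }
  utils::write.table(format(records, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path TSV path; `#` comment lines are skipped.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}
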