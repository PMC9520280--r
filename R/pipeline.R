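#' Pipeline configuration
#'
#' Collects every switch of the end-to-end workflow. `comparisons = NULL`
#' enumerates all unordered pairs of groups present in the design (15 under
#' the default six-group design), run separately within each sex.
#'
#' @param condition_by imputation condition definition, `"group_sex"` or
#'   `"group"`; see [impute_missing()].
#' @param percentile imputation percentile (default 0.01).
#' @param comparisons optional list of `c(condition_a, condition_b)` pairs.
#' @param q_threshold,z_threshold dual-criterion call thresholds.
#' @param screen a [screen_config()].
#' @param pca_center,pca_unit_scale,pca_k PCA switches, see [lfq_pca()].
#' @param seed integer recorded in output provenance (the analysis itself
#'   is deterministic; the seed matters when the input is simulated).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(condition_by = "group_sex", percentile = 0.01,
                            comparisons = NULL, q_threshold = 0.05,
                            z_threshold = stats::qnorm(0.975),
                            screen = screen_config(),
                            pca_center = TRUE, pca_unit_scale = TRUE,
                            pca_k = 2, seed = 1L) {
  structure(list(condition_by = condition_by, percentile = percentile,
                 comparisons = comparisons, q_threshold = q_threshold,
                 z_threshold = z_threshold, screen = screen,
                 pca_center = pca_center, pca_unit_scale = pca_unit_scale,
                 pca_k = pca_k, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the [pipeline_config()] and [screen_config()]
#' arguments, with screen settings nested under `screen:`. Unknown keys are
#' rejected so typos do not silently fall back to defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("condition_by", "percentile", "comparisons", "q_threshold",
             "z_threshold", "screen", "pca_center", "pca_unit_scale",
             "pca_k", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    stop("unknown pipeline config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(y$screen)) {
    y$screen <- do.call(screen_config, y$screen)
  }
  if (!is.null(y$comparisons)) {
    y$comparisons <- lapply(y$comparisons, unlist)
  }
  do.call(pipeline_config, y)
}

# order-independent hash of the config for provenance headers
config_hash <- function(config) {
  txt <- paste(deparse(config[order(names(unclass(config)))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% .Machine$integer.max)
}

all_pairs <- function(groups) {
  idx <- utils::combn(length(groups), 2)
  lapply(seq_len(ncol(idx)), function(j) groups[idx[, j]])
}

#' Run the full post-processing and screening pipeline
#'
#' Decoy filtering, per-condition imputation, all pairwise differential
#' comparisons within each sex, per-sex covariate correlation screens,
#' cross-sex set algebra, and PCA. Sexes are processed as independent
#' analyses and merged only at the set-algebra step.
#'
#' @param protein_table an `lfq_matrix` (linear scale) or a path readable
#'   by [read_protein_table()].
#' @param design a design data.frame or a path readable by [read_design()].
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every stage output is
#'   written as a TSV with a provenance header plus a `manifest.yaml`. On a
#'   stage failure a `FAILED` marker naming the stage is left there.
#' @return the output bundle: list with `imputed`, `imputation_report`,
#'   `diff_records`, `calls`, `screen_records`, `screen_sets`, `pca`,
#'   `config`, `provenance`.
#' @export
run_pipeline <- function(protein_table, design, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "ingest"
  fail <- function(e) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      writeLines(paste("stage:", stage), file.path(out_dir, "FAILED"))
    }
    stop("pipeline stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  }
  withCallingHandlers({
    if (is.character(protein_table)) {
      protein_table <- read_protein_table(protein_table)
    }
    if (is.character(design)) design <- read_design(design)
    design <- validate_design(design)

    stage <- "preprocess"
    mat <- filter_decoys(protein_table)
    if (nrow(mat$values) == 0) stop("no proteins left after decoy filtering")
    imp <- impute_missing(mat, design, condition_by = config$condition_by,
                          percentile = config$percentile)
    imputed <- imp$matrix

    stage <- "diffexpr"
    sexes <- sort(unique(design$sex))
    comparisons <- config$comparisons
    if (is.null(comparisons)) comparisons <- all_pairs(unique(design$group))
    diff_records <- do.call(rbind, unlist(lapply(sexes, function(s) {
      lapply(comparisons, function(pair) {
        run_comparison(imputed, design, pair[1], pair[2], sex = s,
                       q_threshold = config$q_threshold,
                       z_threshold = config$z_threshold)
      })
    }), recursive = FALSE))
    calls <- aggregate_calls(diff_records)

    stage <- "corr_screen"
    screen_records <- lapply(stats::setNames(sexes, sexes), function(s) {
      correlation_screen(imputed, design, sex = s, config = config$screen)
    })
    screen_sets <- screen_and_intersect(screen_records)

    stage <- "pca"
    pca <- lfq_pca(log2_transform(imputed), center = config$pca_center,
                   unit_scale = config$pca_unit_scale, k = config$pca_k)
  }, error = fail)

  bundle <- list(imputed = imputed, imputation_report = imp$report,
                 diff_records = diff_records, calls = calls,
                 screen_records = screen_records, screen_sets = screen_sets,
                 pca = pca, design = design, config = config,
                 provenance = c(seed = as.character(config$seed),
                                config_hash = config_hash(config)))
  if (!is.null(out_dir)) {
    stage <- "write"
    withCallingHandlers(write_bundle(bundle, out_dir), error = fail)
  }
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- bundle$provenance
  write_results(bundle$imputation_report,
                file.path(out_dir, "imputation_report.tsv"), prov)
  write_results(bundle$diff_records,
                file.path(out_dir, "differential_records.tsv"), prov)
  write_results(do.call(rbind, lapply(names(bundle$screen_records), function(s) {
    cbind(sex = s, bundle$screen_records[[s]])
  })), file.path(out_dir, "correlation_screen.tsv"), prov)
  scores <- data.frame(sample_id = rownames(bundle$pca$scores),
                       bundle$pca$scores, check.names = FALSE)
  write_results(scores, file.path(out_dir, "pca_scores.tsv"), prov)
  write_results(pipeline_report(bundle),
                file.path(out_dir, "report_counts.tsv"), prov)
  manifest <- list(seed = unname(prov[["seed"]]),
                   config_hash = unname(prov[["config_hash"]]),
                   n_proteins = nrow(bundle$imputed$values),
                   n_samples = ncol(bundle$imputed$values),
                   n_comparisons = length(unique(bundle$diff_records$comparison)),
                   stages = c("ingest", "preprocess", "diffexpr",
                              "corr_screen", "pca", "write"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  if (file.exists(file.path(out_dir, "FAILED"))) {
    unlink(file.path(out_dir, "FAILED"))
  }
  invisible(out_dir)
}

#' Summary count table for a pipeline run
#'
#' A pure function of the bundle: quantifiable proteins per sex (at least
#' one comparison), significant-union sizes per sex and their cross-sex
#' intersection, and positively / negatively correlated counts per sex with
#' the cross-sex common counts — the synthetic analogue of the per-sex
#' significant and correlated protein counts a dose-response study reports.
#'
#' @param bundle result of [run_pipeline()].
#' @return data.frame with `quantity` and `count` columns.
#' @export
pipeline_report <- function(bundle) {
  need <- c("diff_records", "calls", "screen_sets")
  miss <- need[!need %in% names(bundle)]
  if (length(miss)) {
    stop("incomplete bundle: missing stage output(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  rec <- bundle$diff_records
  sexes <- sort(unique(rec$sex))
  quantifiable <- vapply(sexes, function(s) {
    length(unique(rec$protein_id[rec$sex == s &
                                   rec$call != "not_quantifiable"]))
  }, 0L)
  rows <- rbind(
    data.frame(quantity = paste0("quantifiable_", sexes),
               count = quantifiable),
    data.frame(quantity = paste0("significant_union_", names(bundle$calls$union)),
               count = vapply(bundle$calls$union, length, 0L)),
    data.frame(quantity = "significant_intersection",
               count = length(bundle$calls$intersection)),
    data.frame(quantity = names(bundle$screen_sets$sizes),
               count = as.integer(bundle$screen_sets$sizes)))
  row.names(rows) <- NULL
  rows
}
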