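#' Configuration for the synthetic LFQ study generator
#'
#' Describes a simulated dose-response proteomics study: six treatment
#' groups, three replicate animals per group and sex, a continuous
#' per-animal covariate (hepatic ascorbate, ng per mg tissue) whose group
#' means follow the treatment dose, and four protein classes
#' (dose-correlated up, dose-correlated down, sex-differential, null) plus
#' decoy rows. Log2 abundance is linear in the covariate with Gaussian
#' residual noise; cells drop out with a logistic probability decreasing in
#' true log2 intensity (missing-not-at-random, as in real LFQ data).
#'
#' Default covariate group means (0, 5, 15, 120, 150, 150 ng/mg for GL00,
#' GL01, GL05, WT00, GL40, GLR40) are illustrative dose-ordered values, not
#' measured ones.
#'
#' @param n_proteins total simulated rows, decoys included.
#' @param group_labels ordered condition names.
#' @param replicates_per_group animals per (group, sex).
#' @param sexes sex codes.
#' @param covariate_means named vector, group -> mean covariate (ng/mg).
#' @param covariate_sd per-animal Gaussian noise sd on the covariate
#'   (values truncated at 0).
#' @param class_proportions named fractions for pos_corr, neg_corr,
#'   sex_diff, null; must sum to 1. Applied to non-decoy rows by the
#'   largest-remainder method so realised counts match exactly.
#' @param slope_log2_per_unit |slope| of log2 abundance per covariate unit
#'   for the correlated classes (sign by class).
#' @param sex_effect_log2 |log2 shift| applied to males for sex_diff
#'   proteins (sign drawn per protein).
#' @param residual_sd_log2 within-animal residual sd on the log2 scale.
#' @param baseline_mean_log2,baseline_sd_log2 per-protein baseline log2
#'   abundance distribution.
#' @param dropout_midpoint_log2 log2 intensity at which dropout probability
#'   is 0.5.
#' @param dropout_steepness logistic slope of the dropout curve; 0 gives a
#'   constant 0.5 dropout, larger values a sharper left-censoring edge.
#' @param peptide_lambda peptide counts are 1 + Poisson(peptide_lambda).
#' @param single_peptide_fraction fraction of proteins forced to exactly one
#'   peptide, to exercise the >=2-peptide quantifiability rule.
#' @param decoy_fraction fraction of rows flagged reverse or contaminant.
#' @param seed integer seed; identical configs give identical outputs.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 1000,
                       group_labels = c("WT00", "GL00", "GL01", "GL05",
                                        "GL40", "GLR40"),
                       replicates_per_group = 3,
                       sexes = c("F", "M"),
                       covariate_means = c(WT00 = 120, GL00 = 0, GL01 = 5,
                                           GL05 = 15, GL40 = 150, GLR40 = 150),
                       covariate_sd = 10,
                       class_proportions = c(pos_corr = 0.05, neg_corr = 0.05,
                                             sex_diff = 0.10, null = 0.80),
                       slope_log2_per_unit = 0.02,
                       sex_effect_log2 = 1,
                       residual_sd_log2 = 0.5,
                       baseline_mean_log2 = 25,
                       baseline_sd_log2 = 2,
                       dropout_midpoint_log2 = 21,
                       dropout_steepness = 0.8,
                       peptide_lambda = 3,
                       single_peptide_fraction = 0.1,
                       decoy_fraction = 0.05,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              group_labels = group_labels,
              replicates_per_group = as.integer(replicates_per_group),
              sexes = sexes,
              covariate_means = covariate_means,
              covariate_sd = covariate_sd,
              class_proportions = class_proportions,
              slope_log2_per_unit = slope_log2_per_unit,
              sex_effect_log2 = sex_effect_log2,
              residual_sd_log2 = residual_sd_log2,
              baseline_mean_log2 = baseline_mean_log2,
              baseline_sd_log2 = baseline_sd_log2,
              dropout_midpoint_log2 = dropout_midpoint_log2,
              dropout_steepness = dropout_steepness,
              peptide_lambda = peptide_lambda,
              single_peptide_fraction = single_peptide_fraction,
              decoy_fraction = decoy_fraction,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid sim_config: `", field, "` ", why, call. = FALSE)
  }
  if (cfg$n_proteins < 1) bad("n_proteins", "must be >= 1")
  if (cfg$replicates_per_group < 1) bad("replicates_per_group", "must be >= 1")
  if (!all(cfg$group_labels %in% names(cfg$covariate_means)))
    bad("covariate_means", "must name every group label")
  if (any(cfg$covariate_means < 0)) bad("covariate_means", "must be >= 0")
  if (cfg$covariate_sd < 0) bad("covariate_sd", "must be >= 0")
  want <- c("pos_corr", "neg_corr", "sex_diff", "null")
  if (!setequal(names(cfg$class_proportions), want))
    bad("class_proportions", "must name pos_corr, neg_corr, sex_diff, null")
  if (any(cfg$class_proportions < 0))
    bad("class_proportions", "must be non-negative")
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9)
    bad("class_proportions", "must sum to 1")
  if (cfg$residual_sd_log2 <= 0) bad("residual_sd_log2", "must be > 0")
  if (cfg$dropout_steepness < 0) bad("dropout_steepness", "must be >= 0")
  if (cfg$decoy_fraction < 0 || cfg$decoy_fraction >= 1)
    bad("decoy_fraction", "must be in [0, 1)")
  if (cfg$single_peptide_fraction < 0 || cfg$single_peptide_fraction > 1)
    bad("single_peptide_fraction", "must be in [0, 1]")
  invisible(cfg)
}

#' Generate the study design table
#'
#' One sample per (sex, group, replicate); the per-animal covariate is drawn
#' as the group mean plus Gaussian noise, truncated at zero. Deterministic
#' under the config seed. With defaults this reproduces the 6-group x
#' 3-replicate x 2-sex layout: 36 samples, 18 per sex.
#'
#' @param config a `sim_config`.
#' @return data.frame with columns `sample_id`, `group`, `sex`, `covariate`.
#' @export
make_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  grid <- expand.grid(replicate = seq_len(config$replicates_per_group),
                      group = config$group_labels,
                      sex = config$sexes,
                      stringsAsFactors = FALSE)
  cov <- pmax(0, stats::rnorm(nrow(grid),
                              mean = config$covariate_means[grid$group],
                              sd = config$covariate_sd))
  data.frame(sample_id = sprintf("%s_%s_R%d", grid$sex, grid$group,
                                 grid$replicate),
             group = grid$group,
             sex = grid$sex,
             covariate = unname(cov),
             stringsAsFactors = FALSE)
}

# largest-remainder apportionment of n rows among proportions
largest_remainder <- function(n, proportions) {
  quota <- n * proportions
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}

#' Simulate an LFQ intensity matrix with known ground truth
#'
#' For each protein, log2 intensity in animal j is
#' `baseline + slope * covariate_j + sex_shift * [male] + N(0, residual_sd)`;
#' linear intensities are 2 to that power. Each cell is then set missing
#' with probability `plogis(-steepness * (log2 intensity - midpoint))`, so
#' lower-abundance cells drop out preferentially. Decoy rows (simulated as
#' null proteins) are flagged reverse or contaminant alternately. Peptide
#' counts follow 1 + Poisson(lambda) with a configurable single-peptide
#' fraction. Deterministic under the config seed.
#'
#' @param config a `sim_config`.
#' @param design the design produced by [make_design()] from the same config.
#' @return list with elements:
#'   \describe{
#'     \item{matrix}{`lfq_matrix` on the linear scale, NA = dropped out.}
#'     \item{truth}{data.frame `protein_id`, `class`
#'       (pos_corr/neg_corr/sex_diff/null/decoy), `slope_log2`,
#'       `sex_effect_log2`, `baseline_log2`.}
#'     \item{true_log2}{complete (pre-dropout) log2 intensity matrix, for
#'       recovery and missingness diagnostics.}
#'   }
#' @export
simulate_matrix <- function(config, design) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  need <- c("sample_id", "group", "sex", "covariate")
  if (!all(need %in% names(design)))
    stop("design/config mismatch: design lacks columns ",
         paste(setdiff(need, names(design)), collapse = ", "), call. = FALSE)
  tab <- table(design$group, design$sex)
  if (!setequal(rownames(tab), config$group_labels) ||
      !setequal(colnames(tab), config$sexes) ||
      !all(tab == config$replicates_per_group))
    stop("design/config mismatch: design does not have ",
         config$replicates_per_group, " replicates for every (group, sex)",
         call. = FALSE)

  set.seed(config$seed + 1L)
  n <- config$n_proteins
  n_decoy <- round(config$decoy_fraction * n)
  counts <- largest_remainder(n - n_decoy, config$class_proportions)
  classes <- sample(c(rep(names(counts), counts), rep("decoy", n_decoy)))

  protein_id <- sprintf("P%05d", seq_len(n))
  baseline <- stats::rnorm(n, config$baseline_mean_log2, config$baseline_sd_log2)
  slope <- ifelse(classes == "pos_corr", config$slope_log2_per_unit,
                  ifelse(classes == "neg_corr", -config$slope_log2_per_unit, 0))
  sex_shift <- ifelse(classes == "sex_diff",
                      sample(c(-1, 1), n, replace = TRUE) * config$sex_effect_log2,
                      0)

  m <- nrow(design)
  male <- as.numeric(design$sex == "M")
  mu <- outer(baseline, rep(1, m)) +
    outer(slope, design$covariate) +
    outer(sex_shift, male)
  true_log2 <- mu + matrix(stats::rnorm(n * m, 0, config$residual_sd_log2), n, m)
  colnames(true_log2) <- design$sample_id
  rownames(true_log2) <- protein_id

  p_miss <- stats::plogis(-config$dropout_steepness *
                            (true_log2 - config$dropout_midpoint_log2))
  dropped <- matrix(stats::runif(n * m), n, m) < p_miss
  values <- 2^true_log2
  values[dropped] <- NA_real_

  peptides <- 1L + stats::rpois(n, config$peptide_lambda)
  peptides[stats::runif(n) < config$single_peptide_fraction] <- 1L
  is_decoy <- classes == "decoy"
  decoy_kind <- integer(n)
  decoy_kind[is_decoy] <- seq_len(sum(is_decoy))
  proteins <- data.frame(protein_id = protein_id,
                         gene_name = sprintf("Gene%d", seq_len(n)),
                         peptide_count = peptides,
                         is_reverse = is_decoy & decoy_kind %% 2 == 1,
                         is_contaminant = is_decoy & decoy_kind %% 2 == 0,
                         stringsAsFactors = FALSE)

  truth <- data.frame(protein_id = protein_id,
                      class = classes,
                      slope_log2 = slope,
                      sex_effect_log2 = sex_shift,
                      baseline_log2 = baseline,
                      stringsAsFactors = FALSE)

  list(matrix = lfq_matrix(values, proteins, scale = "linear"),
       truth = truth,
       true_log2 = true_log2)
}

#' Simulate a complete study (design + matrix + truth)
#'
#' Convenience wrapper: [make_design()] then [simulate_matrix()].
#'
#' @param config a `sim_config`.
#' @return list with `design`, `matrix`, `truth`, `true_log2`.
#' @export
simulate_study <- function(config = sim_config()) {
  design <- make_design(config)
  sim <- simulate_matrix(config, design)
  c(list(design = design), sim)
}

#' Write a simulated study as on-disk fixtures
#'
#' Emits the protein table in the MaxQuant proteinGroups dialect read by
#' [read_protein_table()], the design TSV read by [read_design()], and the
#' ground-truth TSV.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_sim_fixture <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(protein_table = file.path(dir, "proteinGroups.txt"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_protein_table(study$matrix, paths[["protein_table"]])
  utils::write.table(study$design, paths[["design"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
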