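# Shared fixture builders: everything is constructed in code at test time.

# minimal design: one row per (sex, group, replicate)
tiny_design <- function(groups = c("A", "B"), sexes = "F", reps = 3,
                        covariate_by_group = NULL) {
  grid <- expand.grid(replicate = seq_len(reps), group = groups,
                      sex = sexes, stringsAsFactors = FALSE)
  cov <- if (is.null(covariate_by_group)) seq_len(nrow(grid))
         else covariate_by_group[grid$group]
  data.frame(sample_id = sprintf("%s_%s_R%d", grid$sex, grid$group,
                                 grid$replicate),
             group = grid$group, sex = grid$sex,
             covariate = unname(cov), stringsAsFactors = FALSE)
}

# lfq_matrix from a bare numeric matrix; metadata defaults are benign
tiny_matrix <- function(values, design, peptide_count = NULL,
                        is_reverse = NULL, is_contaminant = NULL,
                        scale = "linear") {
  values <- as.matrix(values)
  n <- nrow(values)
  colnames(values) <- design$sample_id[seq_len(ncol(values))]
  proteins <- data.frame(
    protein_id = sprintf("T%03d", seq_len(n)),
    gene_name = sprintf("g%d", seq_len(n)),
    peptide_count = if (is.null(peptide_count)) rep(3L, n) else peptide_count,
    is_reverse = if (is.null(is_reverse)) rep(FALSE, n) else is_reverse,
    is_contaminant = if (is.null(is_contaminant)) rep(FALSE, n)
                     else is_contaminant,
    stringsAsFactors = FALSE)
  lfq_matrix(values, proteins, scale = scale)
}

# generator settings with dropout effectively disabled
no_dropout <- function(...) {
  sim_config(dropout_midpoint_log2 = -Inf, dropout_steepness = 1, ...)
}

# independent quadratic-time BH step-up oracle:
# q_i = min(1, min over j with p_(j) >= p_i of p_(j) * m / j)
bh_oracle <- function(p) {
  m <- length(p)
  ps <- sort(p)
  ratio <- ps * m / seq_len(m)
  vapply(p, function(pi) min(1, min(ratio[ps >= pi])), 0)
}

# one-sex study with controllable per-protein structure for gate tests
screen_fixture <- function() {
  cfg <- no_dropout(n_proteins = 6, seed = 3, covariate_sd = 5)
  design <- make_design(cfg)
  design <- design[design$sex == "F", ]
  x <- design$covariate
  base <- 2^25
  vals <- rbind(
    base * 2^(0.02 * x),                   # strong positive, fold 8
    base * 2^(-0.02 * x),                  # strong negative
    base * 2^(0.02 * x),                   # positive but high-missing
    base * 2^(0.004 * x),                  # r high, fold only ~1.5
    base * (1 + 0.001 * ((1:18) %% 3)),    # null-ish
    base * 2^(0.02 * x))                   # positive, single gate test
  m <- tiny_matrix(vals, design)
  m$raw_mask[3, 1:6] <- TRUE  # missing in 6 of 18 samples
  list(matrix = m, design = design)
}

# independent linear-interpolation percentile oracle
percentile_oracle <- function(x, prob) {
  x <- sort(x)
  h <- (length(x) - 1) * prob + 1
  lo <- floor(h)
  if (lo == length(x)) return(x[lo])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}
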