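#!/usr/bin/env Rscript

# Thin command-line front end over the package's functions:
#   Rscript scripts/pipeline.R simulate --seed 1 --n-proteins 1000 --out dir/
#   Rscript scripts/pipeline.R run --proteins proteinGroups.txt \
#       --design design.tsv [--config pipeline.yaml] --out dir/
#   Rscript scripts/pipeline.R report --bundle dir/

suppressPackageStartupMessages({
  library(optparse)
  library(lfqscreen)
})

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) {
  stop("usage: pipeline.R <simulate|run|report> [options]", call. = FALSE)
}
cmd <- args[1]
rest <- args[-1]

status <- tryCatch({
  if (cmd == "simulate") {
    o <- parse_args(OptionParser(option_list = list(
      make_option("--seed", type = "integer", default = 1L),
      make_option("--n-proteins", dest = "n_proteins", type = "integer",
                  default = 1000L),
      make_option("--out", type = "character", default = "sim/")
    )), args = rest)
    st <- simulate_study(sim_config(n_proteins = o$n_proteins, seed = o$seed))
    paths <- write_sim_fixture(st, o$out)
    message("wrote ", paste(paths, collapse = ", "))
  } else if (cmd == "run") {
    o <- parse_args(OptionParser(option_list = list(
      make_option("--proteins", type = "character"),
      make_option("--design", type = "character"),
      make_option("--config", type = "character", default = NULL),
      make_option("--out", type = "character", default = "results/")
    )), args = rest)
    cfg <- if (is.null(o$config)) pipeline_config()
           else read_pipeline_config(o$config)
    run_pipeline(o$proteins, o$design, config = cfg, out_dir = o$out)
    message("pipeline completed; outputs in ", o$out)
  } else if (cmd == "report") {
    o <- parse_args(OptionParser(option_list = list(
      make_option("--bundle", type = "character")
    )), args = rest)
    counts <- read_results(file.path(o$bundle, "report_counts.tsv"))
    print(counts, row.names = FALSE)
  } else {
    stop("unknown subcommand: ", cmd, call. = FALSE)
  }
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})

quit(status = status)
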