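#!/usr/bin/env Rscript

## Thin command-line wrapper around oralcore::run_pipeline().
##
## Usage:
##   Rscript scripts/pipeline.R --out <dir> [--config <yaml>]
##       [--input <dataset dir>] [--seed <int>]
##
## Without --config the study-default configuration is used; --input
## switches from simulation to an on-disk dataset; --seed overrides the
## root seed.

suppressPackageStartupMessages({
  library(optparse)
  library(oralcore)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--out", type = "character", default = "pipeline_out",
              help = "output directory [default %default]"),
  make_option("--config", type = "character", default = NULL,
              help = "YAML configuration (see read_pipeline_config)"),
  make_option("--input", type = "character", default = NULL,
              help = "existing dataset directory (overrides simulation)"),
  make_option("--seed", type = "integer", default = NULL,
              help = "root seed override"))))

cfg <- if (is.null(opts$config)) pipeline_config() else
  read_pipeline_config(opts$config)
if (!is.null(opts$input)) cfg$input_dir <- opts$input
if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)

manifest <- run_pipeline(cfg, opts$out)
cat(sprintf("pipeline complete: %d artifacts in %s\n",
            nrow(manifest$artifacts), opts$out))
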