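#!/usr/bin/env Rscript
# Thin command-line wrapper over the misilk stage runners.
#
# Usage:
#   Rscript spidroin-pipeline.R <subcommand> [options]
# Subcommands:
#   profile    --fasta FILE                 sequence architecture report
#   correlate  --traits FILE --x COL --y COL [--tree FILE]
#   expression --reads FILE --refs FILE
#   simulate                                synthetic dataset bundle
# Global options: --seed INT (default 1), --out DIR (default ./misilk_out)

suppressPackageStartupMessages(library(misilk))

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) {
  message("usage: spidroin-pipeline.R <profile|correlate|expression|simulate> [--key value ...]")
  quit(status = 2)
}
cmd <- args[1]
opts <- list(seed = 1L, out = "misilk_out")
kv <- args[-1]
i <- 1L
while (i <= length(kv)) {
  key <- sub("^--", "", kv[i])
  opts[[key]] <- kv[i + 1L]
  i <- i + 2L
}

run <- function() {
  cfg <- misilk_config(seed = as.integer(opts$seed), out_dir = opts$out)
  switch(
    cmd,
    profile = cmd_profile(opts$fasta, cfg),
    correlate = cmd_correlate(opts$traits, x = opts$x, y = opts$y,
                              tree = opts$tree, config = cfg),
    expression = cmd_expression(opts$reads, opts$refs, config = cfg),
    simulate = cmd_simulate(cfg),
    {
      message("unknown subcommand: ", cmd)
      quit(status = 2)
    })
}

status <- tryCatch({
  run()
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  3L
})
quit(status = status)
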