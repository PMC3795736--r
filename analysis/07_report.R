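#!/usr/bin/env Rscript
# Compose the human-readable summary of all stage outputs.
suppressPackageStartupMessages(library(diracnet))

path <- report_run("results/analysis")
cat(readLines(path), sep = "\n")
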