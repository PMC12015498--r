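#!/usr/bin/env Rscript
# Stage 1: render the synthetic study set — 100 single-tuber images per
# origin (SC, GX, FJ, JX; 200 per species), written as PNG with truth masks
# and a manifest. The class prototypes are the package defaults.

library(tuberscope)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
out <- "results/data"

cfg <- synthetic_config(seed = seed)
ds <- generate_dataset(cfg, dir = out)

cat(sprintf("Rendered %d images (%d per origin) into %s\n",
            nrow(ds$manifest), cfg$n_per_origin, out))
print(table(ds$manifest$origin))
print(table(ds$manifest$species))
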