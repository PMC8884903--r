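#!/usr/bin/env Rscript

# Stage 1: generate one realization of the in vivo pooled knockout screen at
# the default desk scale (1000 genes x 6 sgRNAs, 8 mice, 5 target organs,
# 10 pan-organ and 10 single-organ planted suppressors) and write the
# pipeline-ready input files plus the planted ground truth.

library(crisprmet)

seed <- 20260928L
cfg <- screen_sim_config(seed = seed)
sim <- simulate_screen(cfg)
paths <- write_screen_sim(sim, "results/screen_sim")

message("library: ", nrow(sim$library), " sgRNAs / ",
        length(unique(sim$library$gene)), " genes")
message("samples: ", nrow(sim$sheet), " (",
        paste(capture.output(print(table(sim$sheet$compartment))), collapse = " "),
        ")")
message("planted: ", length(sim$truth$planted_pan), " pan-organ + ",
        length(sim$truth$planted_single), " single-organ suppressors")
message("wrote: ", paste(paths, collapse = ", "))
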