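#!/usr/bin/env Rscript
# Stage 1 — lay down the synthetic study.
#
# Builds the toy genome and gene models (one alternative-splicing unit per
# gene: cassette exons, retained introns, competing 5'/3' splice sites),
# branchpoint annotations, a control junction-count library, a qPCR Ct panel
# with dilution series, and a Pol II-style coverage track. Everything
# downstream (stages 02-05) consumes these files or regenerates cohorts with
# the same configuration.

library(snsplice)

outdir <- "results/sim"
cfg <- sim_config(seed = 20240917L, n_genes = 60, read_depth = 150,
                  true_psi = 0.6, effect_subset = 0.25, effect_size = -0.3)
paths <- write_simulation(cfg, outdir)

ann <- sim_annotation(cfg)
message("genes: ", nrow(ann$genes), " (",
        paste(names(table(ann$genes$kind)), table(ann$genes$kind),
              sep = "=", collapse = ", "), ")")
message("events: ", nrow(ann$events), "; branchpoints: ",
        nrow(ann$branchpoints))
message("genome: ", nchar(ann$genome), " nt on ", names(ann$genome))
message("written: ", paste(basename(paths), collapse = ", "))
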