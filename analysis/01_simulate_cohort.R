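#!/usr/bin/env Rscript
# Step 1 — build the synthetic study cohort.
#
# Four admixed populations (100 diploids each, three ancestry components)
# on a 100-Mb chromosome with 200 gene models. One 5-Mb region carries
# injected African enrichment (local fraction 0.45 vs the genome-wide
# 0.25), playing the role of a strongly selected MHC-like locus; one trait
# gene set is built from that region and 20 random sets act as negative
# controls. Everything downstream works from the files written here.

library(admixscan)

seed <- 1
out <- "scratch/demo_data"

cfg <- demo_cohort_config(seed = seed)
paths <- write_cohort(cfg, out)

truth <- read.delim(paths$truth)
message("cohort written to ", out)
message("populations: ", paste(names(paths$msp), collapse = ", "))
message(sprintf("injected locus: %s:%d-%d, %s ancestry at f_target = %.2f",
                truth$chrom, truth$start, truth$end, truth$ancestry,
                truth$f_target))
message("genes overlapping the injection: ",
        {
          g <- read_bed(paths$bed)
          paste(g$name[g$start < truth$end & g$end > truth$start],
                collapse = ", ")
        })
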