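#!/usr/bin/env Rscript
# Step 4 — polygenic ancestry enrichment (PAE).
#
# Sums gene-level z_anc over each trait gene set, tests against 10,000
# size-matched permutations per (population, ancestry) family, applies
# BH-FDR, and reports the traits significant with the same ancestry and
# direction in at least two populations. Only the injected trait should
# survive the consensus.

library(admixscan)

data_dir <- "scratch/demo_data"
out <- "results"
pops <- c("CLM_like", "MXL_like", "PEL_like", "PUR_like")
seed <- 1

genes <- read_bed(file.path(data_dir, "genes.bed"))
traits <- read_gmt(file.path(data_dir, "traits.gmt"))
tables <- lapply(pops, function(p) {
  scan_panel(read_msp(file.path(data_dir, paste0(p, ".msp.tsv")),
                      population = p), genes)
})

pae <- pae_scan(tables, traits, n_perm = 10000,
                seed = derive_seed(seed, "pae"))
admixscan:::write_result_table(as.data.frame(pae),
                               file.path(out, "pae.tsv"))
message(nrow(pae), " trait x ancestry x population tests; ",
        sum(!is.na(pae$q) & pae$q < 0.05), " at q < 0.05")

cons <- cross_population_traits(pae, min_pops = 2)
admixscan:::write_result_table(cons, file.path(out, "pae_consensus.tsv"))
message("cross-population consensus traits:")
print(cons, row.names = FALSE)
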