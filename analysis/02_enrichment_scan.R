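#!/usr/bin/env Rscript
# Step 2 — single-locus ancestry enrichment scan and cross-population
# combination.
#
# Reads the cohort from step 1, computes per-gene ancestry fractions and
# enrichment z-scores in each population, combines the one-sided evidence
# across the four populations with Fisher's method (chi-square, 2k df) and
# applies BH-FDR. The injected MHC-like genes should dominate the African
# enrichment ranking.

library(admixscan)

data_dir <- "scratch/demo_data"
out <- "results"
pops <- c("CLM_like", "MXL_like", "PEL_like", "PUR_like")

genes <- read_bed(file.path(data_dir, "genes.bed"))
tables <- lapply(pops, function(p) {
  scan_panel(read_msp(file.path(data_dir, paste0(p, ".msp.tsv")),
                      population = p), genes)
})
for (i in seq_along(pops)) {
  admixscan:::write_result_table(
    as.data.frame(tables[[i]]),
    file.path(out, paste0("scores_", pops[i], ".tsv")))
}

universe <- finalize_gene_universe(tables)
message(length(universe), " of ", nrow(genes),
        " genes retained for combination")

for (dir in c("enrich", "deplete")) {
  comb <- fisher_combine(tables, universe, dir)
  admixscan:::write_result_table(as.data.frame(comb),
                                 file.path(out,
                                           paste0("combined_", dir,
                                                  ".tsv")))
  hits <- comb[!is.na(comb$q) & comb$reject, ]
  message(dir, ": ", nrow(hits), " gene x ancestry hits at q < 0.05")
}

comb <- read.delim(file.path(out, "combined_enrich.tsv"))
afr <- comb[comb$ancestry == "AFR", ]
afr <- afr[order(afr$p_chi2), ]
message("top African-enrichment genes:")
print(utils::head(afr[, c("gene", "F_CS", "p_chi2", "q")], 10),
      row.names = FALSE)
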