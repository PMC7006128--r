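single_pop_cfg <- function(theta, n = 50, seed = 1, ...) {
  cohort_config(populations = list(P1 = list(theta = theta, n = n)),
                seed = seed, ...)
}

test_that("a degenerate mixture yields single-ancestry panels", {
  cfg <- single_pop_cfg(c(AFR = 1, EUR = 0, NAT = 0), n = 5,
                        unassigned_rate = 0)
  panel <- generate_panel(cfg, "P1")
  for (h in panel$haplotypes) expect_identical(unique(h$anc), 0L)
})

test_that("the same seed reproduces byte-identical panels", {
  cfg <- cohort_config(seed = 99)
  p1 <- generate_panel(cfg, "CLM_like")
  p2 <- generate_panel(cfg, "CLM_like")
  expect_identical(p1, p2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_msp(p1, f1); write_msp(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # trait sets too
  genes <- generate_genes(cfg)
  t1 <- generate_trait_sets(cfg, genes, 5, 8)
  t2 <- generate_trait_sets(cfg, genes, 5, 8)
  expect_identical(t1, t2)
})

test_that("genome-wide tract ancestry fractions match theta", {
  theta <- c(AFR = 0.3, EUR = 0.5, NAT = 0.2)
  cfg <- single_pop_cfg(theta, n = 200, seed = 3, unassigned_rate = 0,
                        chrom_length_bp = 2e8, cM_per_Mb = 1)
  panel <- generate_panel(cfg, "P1", merge = FALSE)
  anc <- unlist(lapply(panel$haplotypes, `[[`, "anc"))
  n_tr <- length(anc)
  for (k in 0:2) {
    frac <- mean(anc == k)
    se <- sqrt(theta[k + 1] * (1 - theta[k + 1]) / n_tr)
    expect_lt(abs(frac - theta[k + 1]), 4 * se)
  }
})

test_that("mean raw tract genetic length is close to 1/g Morgans", {
  cfg <- single_pop_cfg(c(A = 0.5, B = 0.5), n = 100, seed = 7, g = 10,
                        unassigned_rate = 0, chrom_length_bp = 2e9,
                        cM_per_Mb = 1.3)
  panel <- generate_panel(cfg, "P1", merge = FALSE)
  lens <- unlist(lapply(panel$haplotypes, function(h) {
    diff(c(0, bp_to_cM(panel$map, h$ends))) / 100
  }))
  expect_gt(length(lens), 1e4)
  se <- stats::sd(lens) / sqrt(length(lens))
  # finite chromosome: expected mean is L/(gL+1), indistinguishable from
  # 1/g at this map length
  expect_lt(abs(mean(lens) - 0.1), 3 * se + 1e-3)
})

test_that("injected loci attain the target local ancestry fraction", {
  fracs <- vapply(1:8, function(r) {
    cfg <- cohort_config(
      populations = list(P1 = list(theta = c(AFR = 0.25, EUR = 0.5,
                                             NAT = 0.25), n = 100)),
      chrom = "chr6", chrom_length_bp = 1e8, cM_per_Mb = 1,
      injections = list(list(start = 4e7, end = 4.5e7, ancestry = "AFR",
                             f_target = 0.45)),
      seed = 100 + r)
    panel <- generate_panel(cfg, "P1")
    afr <- 0; tot <- 0
    for (h in panel$haplotypes) {
      starts <- c(0, h$ends[-length(h$ends)])
      lo <- pmax(starts, 4e7); hi <- pmin(h$ends, 4.5e7)
      w <- pmax(hi - lo, 0)
      afr <- afr + sum(w[h$anc == 0L])
      tot <- tot + sum(w[h$anc >= 0L])
    }
    afr / tot
  }, 0)
  se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.45), 4 * se)
})

test_that("the unassigned tract mass matches the configured rate", {
  cfg <- single_pop_cfg(c(A = 0.5, B = 0.5), n = 200, seed = 11,
                        unassigned_rate = 0.05)
  panel <- generate_panel(cfg, "P1", merge = FALSE)
  anc <- unlist(lapply(panel$haplotypes, `[[`, "anc"))
  u_hat <- mean(anc == -1L)
  se <- sqrt(0.05 * 0.95 / length(anc))
  expect_lt(abs(u_hat - 0.05), 4 * se)
})

test_that("gene models are disjoint, sorted and validated", {
  cfg <- single_pop_cfg(c(A = 0.5, B = 0.5), chrom_length_bp = 1e6,
                        gene_count = 10, gene_width = 5e4)
  genes <- generate_genes(cfg)
  expect_equal(nrow(genes), 10)
  expect_false(is.unsorted(genes$start, strictly = TRUE))
  expect_true(all(genes$start[-1] >= genes$end[-10]))
  expect_true(all(genes$end - genes$start == 5e4))
  expect_error(generate_trait_sets(cfg, genes, 2, 11), "set_size")
})

test_that("the enriched trait set lies inside the injection interval", {
  cfg <- demo_cohort_config(seed = 5)
  genes <- generate_genes(cfg)
  traits <- generate_trait_sets(cfg, genes, 3, 10, enriched_trait = "hit")
  inj <- cfg$injections[[1]]
  hit_genes <- genes[match(traits$hit$genes, genes$name), ]
  expect_true(all(hit_genes$start < inj$end & hit_genes$end > inj$start))
  # negative-control sets avoid the injected interval entirely
  for (nm in setdiff(names(traits), "hit")) {
    tg <- genes[match(traits[[nm]]$genes, genes$name), ]
    expect_true(all(tg$end <= inj$start | tg$start >= inj$end))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(single_pop_cfg(c(A = 0.6, B = 0.5)), "sum to 1")
  expect_error(cohort_config(injections = list(
    list(start = -5, end = 10, ancestry = "AFR", f_target = 0.4))),
    "outside")
  expect_error(cohort_config(injections = list(
    list(start = 0, end = 10, ancestry = "AFR", f_target = 1.2))),
    "f_target")
  expect_error(single_pop_cfg(c(A = 0.5, B = 0.5), gene_count = 100,
                              gene_width = 1e6, chrom_length_bp = 1e7),
               "exceeds")
})

test_that("written cohorts are independently re-readable", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(seed = 2, chrom_length_bp = 1e7, gene_count = 20)
  paths <- write_cohort(cfg, dir, n_traits = 3, set_size = 5)
  expect_length(paths$msp, 4)
  for (p in names(paths$msp)) {
    panel <- read_msp(paths$msp[[p]], population = p)
    expect_s3_class(panel, "haplotype_panel")
    expect_identical(panel$palette$labels, c("AFR", "EUR", "NAT"))
  }
  expect_equal(nrow(read_bed(paths$bed)), 20)
  expect_length(read_gmt(paths$gmt), 3)
})
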