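test_that("gene-wise null draws have binomial moments", {
  set.seed(77)
  counts <- admixscan:::.rmultinom_rows(rep(200L, 5000),
                                        c(0.3, 0.5, 0.2))
  f <- counts / 200
  expect_equal(rowSums(counts), rep(200, 5000))
  # per-gene f_AFR: mean 0.3, sd sqrt(0.3*0.7/200) ~ 0.0324
  se_mean <- 0.0324 / sqrt(5000)
  expect_lt(abs(mean(f[, 1]) - 0.3), 3 * se_mean)
  expect_lt(abs(stats::sd(f[, 1]) - sqrt(0.3 * 0.7 / 200)), 3 * 0.002)
})

test_that("gene-wise null ensembles are reproducible and flag degeneracy", {
  h <- matrix(100L, 20, 2)
  th <- list(c(A = 0.3, B = 0.5, C = 0.2), c(A = 0.2, B = 0.6, C = 0.2))
  e1 <- genewise_null(h, th, R = 3, seed = 42)
  e2 <- genewise_null(h, th, R = 3, seed = 42)
  expect_identical(e1, e2)
  expect_false(anyNA(e1$fcs))
  # a degenerate theta component makes that ancestry undefined
  th0 <- list(c(A = 1, B = 0, C = 0), c(A = 1, B = 0, C = 0))
  e0 <- genewise_null(h, th0, R = 2, seed = 1)
  expect_true(all(is.na(e0$fcs)))  # sigma = 0 for every ancestry
})

test_that("the empirical p estimator has its defining properties", {
  ens <- structure(list(fcs = array(as.numeric(1:19999),
                                    dim = c(19999, 1, 1)),
                        mode = "per_gene", R = 1, seed = 1),
                   class = "null_ensemble")
  # observed above all nulls with a pool of 19,999: p = 1/20,000
  expect_equal(empirical_p(2e4, ens), 1 / 20000)
  # observed below everything: p = 1
  expect_equal(empirical_p(-Inf, ens), 1)
  # tie with a single null value counts toward the null: p = 1
  ens1 <- structure(list(fcs = array(5, dim = c(1, 1, 1)),
                         mode = "per_gene", R = 1, seed = 1),
                    class = "null_ensemble")
  expect_equal(empirical_p(5, ens1), 1)
  # estimator bounds and no exact zeros
  set.seed(5)
  obs <- runif(100, -10, 2e4 + 10)
  p <- empirical_p(obs, ens)
  expect_true(all(p >= 1 / 20000 & p <= 1))
  # mode mismatch errors
  expect_error(empirical_p(1, ens, mode = "max_statistic"), "mode mismatch")
  # max-statistic pool is per-replicate maxima
  ens_max <- structure(list(fcs = array(c(1, 2, 3, 4, 5, 6),
                                        dim = c(3, 1, 2)),
                            mode = "max_statistic", R = 2, seed = 1),
                       class = "null_ensemble")
  expect_equal(empirical_p(4, ens_max), (1 + 1) / 3)  # maxima are 3 and 6
})

test_that("Wright-Fisher founders follow largest-remainder composition", {
  cfg <- wf_config(N = 10, generations = 0,
                   theta = c(A = 0.34, B = 0.33, C = 0.33), seed = 1)
  panel <- wright_fisher_sim(cfg)
  # per-diploid ancestry (both haplotypes agree); counts are 4/3/3
  anc <- vapply(panel$haplotypes[seq(1, 19, 2)], function(h) h$anc[1], 0L)
  expect_equal(as.integer(table(factor(anc, 0:2))), c(4L, 3L, 3L))
  for (h in panel$haplotypes) expect_length(unique(h$anc), 1)
})

test_that("gamete crossovers are Poisson with mean = map length", {
  map <- recomb_map(2e8, 1)  # 2 Morgans
  span <- c(0, 2e8)
  hA <- list(ends = 2e8, anc = 0L)
  hB <- list(ends = 2e8, anc = 1L)
  set.seed(12)
  ncx <- vapply(1:10000, function(i) {
    g <- admixscan:::.gamete(hA, hB, 200, map, span)
    length(g$ends) - 1L  # breakpoints = crossovers for distinct parents
  }, 0L)
  se <- stats::sd(ncx) / sqrt(length(ncx))
  expect_lt(abs(mean(ncx) - 2), 3 * se)
})

test_that("Wright-Fisher haplotypes tile the chromosome at every generation", {
  cfg <- wf_config(N = 12, generations = 6,
                   theta = c(A = 0.5, B = 0.3, C = 0.2),
                   chrom_length_bp = 5e7, seed = 31)
  panel <- wright_fisher_sim(cfg, check = TRUE)  # validates each generation
  expect_true(validate_haplotype_panel(panel))
  for (h in panel$haplotypes) {
    expect_equal(sum(diff(c(0, h$ends))), 5e7)
  }
})

test_that("boundary Wright-Fisher configurations behave", {
  expect_error(wf_config(N = 10, sample_size = 11), "sample_size")
  # minimum population size runs end to end
  cfg <- wf_config(N = 2, generations = 3, theta = c(A = 0.5, B = 0.5),
                   chrom_length_bp = 1e7, seed = 2)
  expect_s3_class(wright_fisher_sim(cfg), "haplotype_panel")
  # g = 0 returns founders
  cfg0 <- wf_config(N = 5, generations = 0, theta = c(A = 0.6, B = 0.4),
                    seed = 3)
  p0 <- wright_fisher_sim(cfg0)
  for (h in p0$haplotypes) expect_length(h$ends, 1)
})

test_that("neutral drift preserves the expected ancestry fraction", {
  fr <- vapply(1:30, function(r) {
    cfg <- wf_config(N = 50, generations = 8,
                     theta = c(A = 0.3, B = 0.7), chrom_length_bp = 5e7,
                     seed = 500 + r)
    panel_ancestry_fractions(wright_fisher_sim(cfg))[["A"]]
  }, 0)
  se <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.3), 4 * se)
})

test_that("chromosome-scale null ensembles are reproducible", {
  genes <- data.frame(chrom = "c", start = seq(0, 9e6, 1e6),
                      end = seq(0, 9e6, 1e6) + 5e5,
                      name = sprintf("g%02d", 1:10))
  cfgs <- list(
    P1 = wf_config(N = 30, generations = 5,
                   theta = c(A = 0.4, B = 0.4, C = 0.2),
                   chrom_length_bp = 1e7),
    P2 = wf_config(N = 30, generations = 5,
                   theta = c(A = 0.3, B = 0.5, C = 0.2),
                   chrom_length_bp = 1e7))
  e1 <- suppressWarnings(chromosome_null(cfgs, genes, R = 2, seed = 6))
  e2 <- suppressWarnings(chromosome_null(cfgs, genes, R = 2, seed = 6))
  expect_identical(e1, e2)
  expect_true(any(is.finite(e1$fcs)))
})

test_that("combined-test power is calibrated at null and saturates", {
  th <- list(c(A = 0.25, B = 0.5, C = 0.25), c(A = 0.25, B = 0.45, C = 0.3))
  # null case: f_target equal to theta -> power ~ alpha
  pw0 <- power_analysis(0.25, th, n_grid = 500, R = 200, alpha = 0.05,
                        seed = 2)
  expect_lt(abs(pw0$power - 0.05), qnorm(0.995) * sqrt(0.05 * 0.95 / 200))
  # extreme separation: power 1
  pw1 <- power_analysis(1.0, th, n_grid = 10000, R = 20, alpha = 1e-4,
                        seed = 3)
  expect_equal(pw1$power, 1)
})

test_that("cross-population power at the demo effect size is high", {
  th <- lapply(c(0.55, 0.40, 0.30, 0.65), function(e) {
    c(AFR = 0.25, EUR = e, NAT = 1 - 0.25 - e)
  })
  pw <- power_analysis(0.45, th, n_grid = 100, R = 50, alpha = 1e-4,
                       seed = 1)
  expect_gte(pw$power, 0.9)
})
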