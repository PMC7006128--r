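test_that("gene-spanning haplotype counting follows the full-coverage rule", {
  # hap1 all-AFR, hap2 all-EUR, hap3 switches at the gene midpoint,
  # hap4 fully unassigned -> h_tot = 2, h_AFR = h_EUR = 1
  panel <- toy_panel(list(
    list(ends = 200, anc = 0L),
    list(ends = 200, anc = 1L),
    list(ends = c(100, 200), anc = c(0L, 1L)),
    list(ends = 200, anc = -1L)))
  gene <- list(start = 50, end = 150, name = "g")
  cc <- assign_gene_ancestries(panel, gene)
  expect_equal(cc$h_tot, 2L)
  expect_equal(unname(cc$h_anc[c("AFR", "EUR", "NAT")]), c(1L, 1L, 0L))
  expect_equal(cc$h_anc[["AFR"]] / cc$h_tot, 0.5)
})

test_that("single-ancestry chromosomes assign every haplotype to every gene", {
  haps <- lapply(1:6, function(i) list(ends = 200, anc = i %% 3))
  panel <- toy_panel(haps)
  genes <- data.frame(start = c(0, 60, 120), end = c(50, 110, 180),
                      name = c("a", "b", "c"))
  cc <- gene_ancestry_counts(panel, genes)
  expect_true(all(cc$h_tot == 6L))
})

test_that("counting matches per-base brute-force enumeration", {
  set.seed(404)
  for (rep in 1:25) {
    panel <- random_toy_panel()
    m <- sample(1:5, 1)
    start <- sort(sample(0:190, m))
    genes <- data.frame(start = start,
                        end = pmin(start + sample(5:40, m, TRUE), 200),
                        name = paste0("g", seq_len(m)))
    expect_identical(gene_ancestry_counts(panel, genes)$h_anc |> unname(),
                     brute_force_counts(panel, genes)$h_anc)
  }
})

test_that("genes outside the panel span are rejected", {
  panel <- toy_panel(list(list(ends = 200, anc = 0L),
                          list(ends = 200, anc = 1L)))
  expect_error(
    gene_ancestry_counts(panel, data.frame(start = 150, end = 250,
                                           name = "g")),
    "span")
})

test_that("scan standardizes f_anc into calibrated z-scores", {
  cfg <- cohort_config(populations = list(
    P1 = list(theta = c(AFR = 0.3, EUR = 0.5, NAT = 0.2), n = 60)),
    seed = 8, chrom_length_bp = 5e8, gene_count = 80)
  genes <- generate_genes(cfg)
  tab <- scan_panel(generate_panel(cfg, "P1"), genes)
  mu <- attr(tab, "mu_anc"); sigma <- attr(tab, "sigma_anc")
  ok <- tab$retained & !is.na(tab$z_anc)
  # exact standardization identity
  expect_equal(tab$z_anc[ok],
               unname((tab$f_anc[ok] - mu[tab$ancestry[ok]]) /
                        sigma[tab$ancestry[ok]]))
  # mean 0, sd 1 over retained genes by construction
  for (anc in c("AFR", "EUR", "NAT")) {
    z <- tab$z_anc[ok & tab$ancestry == anc]
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(stats::sd(z), 1, tolerance = 1e-9)
  }
  # p-values are the one-sided normal tails of z
  expect_equal(tab$p_enrich[ok], pnorm(tab$z_anc[ok], lower.tail = FALSE))
  expect_equal(tab$p_deplete[ok], pnorm(tab$z_anc[ok]))
  # f_anc sums to 1 over ancestries for assigned genes
  sums <- tapply(tab$f_anc[tab$h_tot > 0], tab$gene[tab$h_tot > 0], sum)
  expect_equal(as.vector(sums), rep(1, length(sums)))
})

test_that("the upper normal tail at z = 2 matches numeric integration", {
  oracle <- integrate(dnorm, 2, Inf)$value  # ~0.02275
  # a gene with f = 0.5 against mu = 0.3, sigma = 0.1 has z = 2
  expect_equal((0.5 - 0.3) / 0.1, 2)
  expect_equal(pnorm(2, lower.tail = FALSE), oracle, tolerance = 1e-8)
  expect_equal(pnorm(0, lower.tail = FALSE), 0.5)
})

test_that("an absent ancestry gets flagged scores, not an error", {
  cfg <- cohort_config(populations = list(
    P1 = list(theta = c(AFR = 0.5, EUR = 0.5, NAT = 0), n = 30)),
    seed = 5, chrom_length_bp = 1e8, gene_count = 30)
  expect_warning(
    tab <- scan_panel(generate_panel(cfg, "P1"), generate_genes(cfg)),
    "sigma_anc = 0")
  expect_true(all(is.na(tab$z_anc[tab$ancestry == "NAT"])))
  expect_false(anyNA(tab$z_anc[tab$ancestry == "AFR" & tab$h_tot > 0]))
})

test_that("the cross-population universe applies the h_tot filter by rule", {
  mk <- function(retained) {
    df <- data.frame(gene = paste0("g", 1:5), retained = retained)
    structure(df, class = c("gene_score_table", "data.frame"))
  }
  t1 <- mk(c(TRUE, TRUE, TRUE, FALSE, TRUE))
  t2 <- mk(c(TRUE, FALSE, TRUE, FALSE, TRUE))
  # at-least-one rule: g4 fails everywhere and is dropped
  expect_identical(finalize_gene_universe(list(t1, t2)),
                   c("g1", "g2", "g3", "g5"))
  # every-population rule: g2 (fails in one population) is also dropped
  expect_identical(finalize_gene_universe(list(t1, t2), rule = "every"),
                   c("g1", "g3", "g5"))
  t3 <- mk(rep(TRUE, 5)); t3$gene <- paste0("x", 1:5)
  expect_error(finalize_gene_universe(list(t1, t3)), "differ")
  t4 <- mk(rep(FALSE, 5))
  expect_error(finalize_gene_universe(list(t4, t4)), "empty")
})

test_that("Fisher combination matches its closed form and identities", {
  # boundary: all p = 1
  fs <- fisher_score(c(1, 1, 1, 1))
  expect_equal(fs$F_CS, 0)
  expect_equal(fs$p_chi2, 1)
  # four p = 0.05 against the even-df closed-form survival oracle
  fs <- fisher_score(rep(0.05, 4))
  expect_equal(fs$F_CS, -2 * 4 * log(0.05), tolerance = 1e-12)
  expect_equal(fs$F_CS, 23.9659, tolerance = 1e-4)
  expect_equal(fs$p_chi2, chisq_sf_even(fs$F_CS, 8), tolerance = 1e-12)
  expect_equal(fs$p_chi2, 2.32e-3, tolerance = 1e-2)
  # single population: chi2 with 2 df survival equals p exactly
  for (p in c(0.9, 0.5, 0.01, 1e-6)) {
    expect_equal(fisher_score(p)$p_chi2, p, tolerance = 1e-12)
  }
  # monotone: decreasing any p_i strictly increases F_CS
  set.seed(9)
  for (rep in 1:20) {
    p <- runif(4)
    i <- sample(4, 1)
    p2 <- p; p2[i] <- p[i] * runif(1)
    expect_gt(fisher_score(p2)$F_CS, fisher_score(p)$F_CS)
  }
  expect_error(fisher_score(c(0.5, 0)), "p = 0")
})

test_that("BH step-up matches a brute-force oracle", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_true(all(r$reject))
  r <- bh_fdr(rep(1, 5))
  expect_true(all(r$q == 1) && !any(r$reject))
  r <- bh_fdr(0.04)
  expect_equal(r$q, 0.04)
  expect_true(r$reject)
  set.seed(31)
  for (rep in 1:20) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    got <- bh_fdr(p)
    want <- bh_stepup_oracle(p)
    expect_equal(got$q, want$q)
    expect_identical(got$reject, want$reject)
  }
  expect_error(bh_fdr(numeric(0)), "at least one")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("score overlays report the max absolute score within flanks", {
  genes <- data.frame(chrom = "c", start = c(100, 300, 500),
                      end = c(200, 400, 600),
                      name = c("a", "b", "c"))
  track <- structure(list(positions = c(150, 320, 340, 350),
                          scores = c(3.1, 2.0, -2.6, 1.0), label = "ihs"),
                     class = "score_track")
  ov <- overlay_scores(genes, track)
  expect_equal(ov$max_abs_score, c(3.1, 2.6, NA))
  expect_identical(ov$above_threshold, c(TRUE, TRUE, FALSE))
  # all sub-threshold scores flag nothing
  track$scores <- c(1.1, 2.0, -2.3, 1.0)
  expect_false(any(overlay_scores(genes, track)$above_threshold))
  # flank pulls neighboring points into range: [300, 800) covers 320-350
  ov <- overlay_scores(genes, track, flank_bp = 200)
  expect_equal(ov$max_abs_score[3], 2.3)
})
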