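# Independent oracles and tiny fixture builders used across the suite.

# Closed-form chi-square survival for even df:
# P(X >= x) = exp(-x/2) * sum_{j=0}^{df/2 - 1} (x/2)^j / j!
chisq_sf_even <- function(x, df) {
  stopifnot(df %% 2 == 0)
  half <- x / 2
  j <- 0:(df / 2 - 1)
  exp(-half) * sum(half^j / factorial(j))
}

# Brute-force Benjamini-Hochberg step-up: find the largest i with
# p_(i) <= i * q / m; reject all p <= p_(i). Adjusted values by direct
# definition with cumulative-minimum correction.
bh_stepup_oracle <- function(p, q_threshold = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- ps * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  q <- numeric(m)
  q[ord] <- adj
  list(q = q, reject = q < q_threshold)
}

# Build a panel from explicit per-haplotype tract specs:
# haps = list of list(ends = , anc = ); length must be even (2 per sample).
toy_panel <- function(haps, span = c(0, 200),
                      labels = c("AFR", "EUR", "NAT"),
                      population = "TOY") {
  stopifnot(length(haps) %% 2 == 0)
  n <- length(haps) / 2
  haplotype_panel(population, sprintf("S%02d", seq_len(n)), haps,
                  ancestry_palette(labels), "chrT", span)
}

# Random toy panel: <= 10 haplotypes with random switch points over a
# short chromosome, random codes including UNASSIGNED.
random_toy_panel <- function(span = c(0, 200), K = 3, max_haps = 10) {
  n_hap <- 2 * sample(1:(max_haps %/% 2), 1)
  haps <- lapply(seq_len(n_hap), function(i) {
    ncx <- sample(0:4, 1)
    cx <- sort(sample(seq(span[1] + 1, span[2] - 1), ncx))
    ends <- unique(c(cx, span[2]))
    anc <- sample(c(-1L, 0:(K - 1L)), length(ends), replace = TRUE,
                  prob = c(0.15, rep(0.85 / K, K)))
    list(ends = ends, anc = anc)
  })
  toy_panel(haps, span = span,
            labels = paste0("A", seq_len(K) - 1))
}

# Per-base brute-force gene ancestry counting: a haplotype counts for
# ancestry a iff every base of the gene has ancestry a (and a != -1).
brute_force_counts <- function(panel, genes) {
  K <- panel$palette$K
  m <- nrow(genes)
  counts <- matrix(0L, m, K)
  for (h in panel$haplotypes) {
    base_anc <- rep(h$anc, times = diff(c(panel$span[1], h$ends)))
    for (gi in seq_len(m)) {
      rel <- (genes$start[gi] - panel$span[1] + 1):(genes$end[gi] -
                                                      panel$span[1])
      a <- unique(base_anc[rel])
      if (length(a) == 1 && a >= 0) counts[gi, a + 1] <- counts[gi, a + 1] + 1L
    }
  }
  list(h_anc = counts, h_tot = as.integer(rowSums(counts)))
}

# Exact moments of a without-replacement sample sum of size k from
# population z: mean = k * mean(z); var = k * (m - k) / m * var(z)
# (var() with the n-1 denominator).
finite_pop_sum_moments <- function(z, k) {
  m <- length(z)
  list(mean = k * mean(z),
       var = k * (m - k) / m * stats::var(z))
}

# Minimal gene_score_table for polygenic tests: one ancestry, all genes
# retained, prescribed z values.
fake_score_table <- function(z, ancestry = "AFR", population = "P1") {
  df <- data.frame(
    population = population,
    gene = sprintf("g%03d", seq_along(z)),
    ancestry = ancestry,
    h_anc = NA_integer_, h_tot = 100L, retained = TRUE,
    f_anc = NA_real_, z_anc = z,
    p_enrich = stats::pnorm(z, lower.tail = FALSE),
    p_deplete = stats::pnorm(z),
    stringsAsFactors = FALSE)
  structure(df, class = c("gene_score_table", "data.frame"),
            population = population, labels = ancestry)
}
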