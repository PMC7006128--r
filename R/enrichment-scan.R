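# Single-locus ancestry enrichment scan.
#
# For each gene and population, a haplotype is counted toward ancestry A iff
# its local-ancestry calls cover the whole gene interval with ancestry A
# (no switch, no unassigned segment inside the gene); other haplotypes
# contribute to neither h_anc nor h_tot. Gene-level ancestry fractions
# f_anc = h_anc / h_tot are standardized against the genome-wide mean and
# standard deviation of f_anc over retained genes, giving the enrichment
# statistic z_anc = (f_anc - mu_anc) / sigma_anc, with one-sided normal
# p-values. Evidence is combined across populations with Fisher's combined
# score F_CS = -2 * sum(ln P_i), chi-square with 2k degrees of freedom, and
# corrected by Benjamini-Hochberg FDR.

# For each haplotype, the gene-spanning ancestry code (NA when the
# haplotype switches ancestry or is unassigned anywhere inside the gene).
.hap_gene_codes <- function(hap, span, gstart, gend) {
  starts <- .hap_starts(hap, span)
  i1 <- findInterval(gstart, starts)
  i2 <- findInterval(gend - 1, starts)
  code <- hap$anc[i1]
  code[i1 != i2 | code < 0L] <- NA_integer_
  code
}

#' Count ancestry-spanning haplotypes for one gene
#'
#' @param panel A [haplotype_panel()].
#' @param gene A single-row gene model (list or data.frame row with
#'   `start`, `end`, `name`).
#' @return List with `gene`, `h_anc` (named integer vector over palette
#'   labels) and `h_tot = sum(h_anc)`.
#' @export
assign_gene_ancestries <- function(panel, gene) {
  cc <- gene_ancestry_counts(panel, data.frame(start = gene$start,
                                               end = gene$end,
                                               name = gene$name))
  list(gene = gene$name, h_anc = cc$h_anc[1, ], h_tot = cc$h_tot[1])
}

#' Count ancestry-spanning haplotypes for many genes
#'
#' @param panel A [haplotype_panel()].
#' @param genes Gene-model data.frame (`start`, `end`, `name`).
#' @return List with `h_anc` (genes x ancestries integer matrix) and
#'   `h_tot` (integer vector).
#' @export
gene_ancestry_counts <- function(panel, genes) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (any(genes$start < panel$span[1]) || any(genes$end > panel$span[2]))
    stop("gene outside the panel chromosome span")
  K <- panel$palette$K
  m <- nrow(genes)
  counts <- matrix(0L, m, K,
                   dimnames = list(genes$name, panel$palette$labels))
  for (h in panel$haplotypes) {
    code <- .hap_gene_codes(h, panel$span, genes$start, genes$end)
    ok <- which(!is.na(code))
    if (length(ok)) {
      idx <- cbind(ok, code[ok] + 1L)
      counts[idx] <- counts[idx] + 1L
    }
  }
  list(h_anc = counts, h_tot = as.integer(rowSums(counts)))
}

#' Per-gene ancestry enrichment scan of one population
#'
#' Computes `f_anc`, standardizes to `z_anc` against the genome-wide mean
#' and SD of `f_anc` over retained genes (sample SD, n-1 denominator), and
#' attaches one-sided normal p-values (`p_enrich` upper tail, `p_deplete`
#' lower tail). A gene is retained iff its `h_tot` lies within one standard
#' deviation of the genome-wide mean `h_tot` (and `h_tot > 0`); genes
#' outside that band still receive scores but are excluded from the
#' genome-wide moments and from downstream combination. Ancestries whose
#' `sigma_anc` is zero (degenerate, e.g. an absent ancestry) get `NA`
#' scores with a warning.
#'
#' @param panel A [haplotype_panel()].
#' @param genes Gene-model data.frame.
#' @return A `gene_score_table`: long data.frame (`population`, `gene`,
#'   `ancestry`, `h_anc`, `h_tot`, `retained`, `f_anc`, `z_anc`,
#'   `p_enrich`, `p_deplete`) with genome-wide moments in attributes
#'   `mu_anc`, `sigma_anc`, `mu_htot`, `sigma_htot`.
#' @export
scan_panel <- function(panel, genes) {
  cc <- gene_ancestry_counts(panel, genes)
  h_tot <- cc$h_tot
  if (sum(h_tot > 0) < 2)
    stop("need at least 2 genes with ancestry-assigned haplotypes")
  mu_htot <- mean(h_tot)
  sigma_htot <- stats::sd(h_tot)
  retained <- h_tot > 0 & abs(h_tot - mu_htot) <= sigma_htot

  f <- cc$h_anc / h_tot  # rows with h_tot == 0 become NaN
  f[h_tot == 0, ] <- NA_real_
  mu <- colMeans(f[retained, , drop = FALSE])
  sigma <- apply(f[retained, , drop = FALSE], 2, stats::sd)
  z <- sweep(sweep(f, 2, mu), 2, sigma, "/")
  degen <- !is.finite(sigma) | sigma == 0
  if (any(degen)) {
    warning("sigma_anc = 0 for ancestry ",
            paste(colnames(f)[degen], collapse = ","),
            " in ", panel$population, "; scores set to NA")
    z[, degen] <- NA_real_
  }
  pe <- stats::pnorm(z, lower.tail = FALSE)
  pd <- stats::pnorm(z)

  K <- panel$palette$K
  labels <- panel$palette$labels
  out <- data.frame(
    population = panel$population,
    gene = rep(genes$name, each = K),
    ancestry = rep(labels, times = nrow(genes)),
    h_anc = as.integer(t(cc$h_anc)),
    h_tot = rep(h_tot, each = K),
    retained = rep(retained, each = K),
    f_anc = as.vector(t(f)),
    z_anc = as.vector(t(z)),
    p_enrich = as.vector(t(pe)),
    p_deplete = as.vector(t(pd)),
    stringsAsFactors = FALSE)
  structure(out,
            class = c("gene_score_table", "data.frame"),
            mu_anc = mu, sigma_anc = sigma,
            mu_htot = mu_htot, sigma_htot = sigma_htot,
            population = panel$population, labels = labels)
}

#' Cross-population retained gene universe
#'
#' A gene enters the combined analysis if it passes the per-population
#' `h_tot` filter (within one SD of the genome-wide mean) in at least one
#' population (`rule = "any"`, the default) or in every population
#' (`rule = "every"`). The one-SD band retains roughly 68% of genes per
#' population, so requiring it everywhere shrinks the universe to ~20%
#' with four populations and routinely drops genuinely enriched loci;
#' the at-least-one rule keeps nearly all genes while still discarding
#' genes whose haplotype assignment is atypical in every population.
#'
#' @param tables List of `gene_score_table`s, one per population, over the
#'   same gene list.
#' @param rule `"any"` (pass in at least one population) or `"every"`.
#' @return Character vector of retained gene names.
#' @export
finalize_gene_universe <- function(tables, rule = c("any", "every")) {
  rule <- match.arg(rule)
  stopifnot(length(tables) >= 1)
  glists <- lapply(tables, function(t) unique(t$gene))
  for (g in glists[-1]) {
    if (!identical(sort(g), sort(glists[[1]])))
      stop("gene lists differ across populations")
  }
  retlists <- lapply(tables, function(t) unique(t$gene[t$retained]))
  keep <- if (rule == "every") Reduce(intersect, retlists)
          else Reduce(union, retlists)
  if (!length(keep)) stop("empty gene universe after h_tot filtering")
  glists[[1]][glists[[1]] %in% keep]
}

#' Fisher's combined score for a vector of p-values
#'
#' @param p Numeric vector of p-values in (0, 1], one per population.
#' @return List with `F_CS = -2 * sum(log(p))`, `df = 2 * length(p)` and
#'   the chi-square survival p-value `p_chi2`.
#' @export
fisher_score <- function(p) {
  if (!length(p) || anyNA(p)) stop("p-values must be non-missing")
  if (any(p <= 0)) stop("Fisher combination undefined for p = 0")
  if (any(p > 1)) stop("p-values must lie in (0, 1]")
  fcs <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(F_CS = fcs, df = df,
       p_chi2 = stats::pchisq(fcs, df = df, lower.tail = FALSE))
}

#' Combine per-population enrichment evidence with Fisher's method
#'
#' For each gene in the universe and each ancestry, combines the one-sided
#' p-values of the chosen direction across populations into
#' `F_CS = -2 * sum(ln P_i)` with a chi-square `2k` df significance test,
#' then applies Benjamini-Hochberg FDR across all gene x ancestry rows of
#' that direction. Ancestries with undefined scores in a population are
#' skipped for that population (with a warning), reducing `k` for that
#' ancestry.
#'
#' @param tables List of `gene_score_table`s (one per population).
#' @param universe Retained gene names; defaults to
#'   [finalize_gene_universe()].
#' @param direction `"enrich"` (upper-tail p-values) or `"deplete"`.
#' @param q_threshold FDR significance threshold (default 0.05).
#' @return A `combined_score_table` data.frame: `gene`, `ancestry`, `k`,
#'   `F_CS`, `p_chi2`, `q`, `reject`, `direction`, `p_empirical` (NA until
#'   filled by a null ensemble).
#' @export
fisher_combine <- function(tables, universe = NULL,
                           direction = c("enrich", "deplete"),
                           q_threshold = 0.05) {
  direction <- match.arg(direction)
  if (is.null(universe)) universe <- finalize_gene_universe(tables)
  pcol <- if (direction == "enrich") "p_enrich" else "p_deplete"
  labels <- attr(tables[[1]], "labels")
  m <- length(universe)
  K <- length(labels)

  # genes x ancestries x populations array of one-sided p-values
  parr <- array(NA_real_, dim = c(m, K, length(tables)))
  for (j in seq_along(tables)) {
    t <- tables[[j]]
    idx <- t$gene %in% universe
    pm <- matrix(t[[pcol]][idx], nrow = K)  # ancestry-major within gene
    colnames(pm) <- unique(t$gene[idx])
    parr[, , j] <- t(pm[, universe, drop = FALSE])
  }
  if (any(parr == 0, na.rm = TRUE))
    stop("Fisher combination undefined for p = 0")
  na_anc <- apply(is.na(parr), 2, any)
  if (any(na_anc))
    warning("undefined scores skipped in combination for ancestry ",
            paste(labels[na_anc], collapse = ","))
  logp <- log(parr)
  fcs <- -2 * apply(logp, c(1, 2), sum, na.rm = TRUE)
  k <- apply(!is.na(parr), c(1, 2), sum)
  fcs[k == 0] <- NA_real_
  p_chi2 <- stats::pchisq(fcs, df = 2 * k, lower.tail = FALSE)

  out <- data.frame(
    gene = rep(universe, times = K),
    ancestry = rep(labels, each = m),
    k = as.vector(k),
    F_CS = as.vector(fcs),
    p_chi2 = as.vector(p_chi2),
    q = NA_real_, reject = NA,
    direction = direction,
    p_empirical = NA_real_,
    stringsAsFactors = FALSE)
  ok <- !is.na(out$p_chi2)
  if (any(ok)) {
    adj <- bh_fdr(out$p_chi2[ok], q_threshold)
    out$q[ok] <- adj$q
    out$reject[ok] <- adj$reject
  }
  structure(out, class = c("combined_score_table", "data.frame"),
            q_threshold = q_threshold)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Standard step-up BH adjustment; a test is rejected when its adjusted
#' value falls below the threshold.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param q_threshold Significance threshold (default 0.05).
#' @return List with `q` (adjusted values) and `reject` (logical).
#' @export
bh_fdr <- function(pvalues, q_threshold = 0.05) {
  if (!length(pvalues)) stop("bh_fdr needs at least one p-value")
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, reject = q < q_threshold)
}

#' Overlay a selection-score track on genes
#'
#' Reports, per gene, the maximum absolute score within the gene interval
#' extended by `flank_bp` on both sides, and whether it reaches the
#' threshold (default 2.5, the conventional |iHS| flag for putative
#' positive selection). Genes with no track points in range get `NA` and
#' `FALSE`.
#'
#' @param genes Gene-model data.frame.
#' @param track A [read_score_track()] object.
#' @param threshold Absolute-score flag threshold.
#' @param flank_bp Flank added to each side of the gene.
#' @return data.frame: `gene`, `max_abs_score`, `above_threshold`,
#'   `n_points`.
#' @export
overlay_scores <- function(genes, track, threshold = 2.5, flank_bp = 0) {
  stopifnot(inherits(track, "score_track"))
  pos <- track$positions
  lo <- genes$start - flank_bp
  hi <- genes$end + flank_bp
  a <- findInterval(lo, pos, left.open = TRUE)   # points strictly before lo
  b <- findInterval(hi, pos, left.open = TRUE)   # points strictly before hi
  mx <- rep(NA_real_, nrow(genes))
  np <- b - a
  for (i in which(np > 0)) {
    mx[i] <- max(abs(track$scores[(a[i] + 1):b[i]]))
  }
  data.frame(gene = genes$name,
             max_abs_score = mx,
             above_threshold = !is.na(mx) & mx >= threshold,
             n_points = np,
             stringsAsFactors = FALSE)
}
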