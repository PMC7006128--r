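# Null distributions of the enrichment statistics under random admixture.
#
# Two routes: (1) gene-wise multinomial draws — each gene's assigned
# haplotypes are redrawn iid from the population's genome-wide ancestry
# fractions, the replicate is re-standardized with its own genome-wide
# moments, and evidence is combined across populations exactly as in the
# observed scan; (2) Wright-Fisher forward simulation with recombination —
# whole admixed populations are simulated forward from single-ancestry
# founders and pushed through the same scan, capturing linkage and drift.

# Row-wise multinomial draws: n[i] trials with probabilities theta,
# implemented as sequential conditional binomials (vectorized over rows).
.rmultinom_rows <- function(n, theta) {
  K <- length(theta)
  out <- matrix(0L, length(n), K)
  rem <- as.integer(n)
  pleft <- 1
  for (k in seq_len(K - 1)) {
    pk <- if (pleft > 0) min(max(theta[k] / pleft, 0), 1) else 0
    x <- stats::rbinom(length(n), rem, pk)
    out[, k] <- x
    rem <- rem - x
    pleft <- pleft - theta[k]
  }
  out[, K] <- rem
  out
}

# One gene-wise null replicate for one population: f, z and one-sided p
# (m genes x K ancestries). Degenerate ancestries (sigma == 0) return NA.
.genewise_pop_p <- function(h_tot, theta, direction) {
  counts <- .rmultinom_rows(h_tot, theta)
  f <- counts / h_tot
  mu <- colMeans(f)
  sigma <- apply(f, 2, stats::sd)
  z <- sweep(sweep(f, 2, mu), 2, sigma, "/")
  z[, !is.finite(sigma) | sigma == 0] <- NA_real_
  p <- if (direction == "enrich") stats::pnorm(z, lower.tail = FALSE)
       else stats::pnorm(z)
  # guard against underflow to exactly 0 (log would be -Inf)
  pmax(p, 1e-320)
}

#' Gene-wise multinomial null ensemble of combined scores
#'
#' For each replicate, gene and population, `h_tot` haplotype ancestries are
#' drawn iid from the population's genome-wide ancestry fractions; `z_anc`
#' is recomputed against the replicate's own gene-wise moments and combined
#' across populations into `F_CS` exactly as in the observed scan.
#'
#' @param h_tot Integer matrix (genes x populations) of assigned-haplotype
#'   totals, typically the observed totals over the retained universe.
#' @param thetas List (one per population, same order as `h_tot` columns)
#'   of genome-wide ancestry fraction vectors.
#' @param R Number of replicates.
#' @param seed Integer seed.
#' @param direction `"enrich"` or `"deplete"`.
#' @param mode `"per_gene"` (pool all null values) or `"max_statistic"`
#'   (pool each replicate's genome-wide maximum; family-wise control).
#' @return A `null_ensemble`: list with `fcs` (genes x ancestries x R
#'   array), `mode`, `R`, `seed`, `direction`.
#' @export
genewise_null <- function(h_tot, thetas, R, seed = 1,
                          direction = c("enrich", "deplete"),
                          mode = c("per_gene", "max_statistic")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  h_tot <- as.matrix(h_tot)
  stopifnot(ncol(h_tot) == length(thetas), R >= 1, all(h_tot >= 1))
  K <- length(thetas[[1]])
  m <- nrow(h_tot)
  labels <- names(thetas[[1]]) %||% paste0("anc", seq_len(K) - 1)
  fcs <- array(NA_real_, dim = c(m, K, R),
               dimnames = list(rownames(h_tot), labels, NULL))
  with_seed(seed, {
    for (r in seq_len(R)) {
      acc <- matrix(0, m, K)
      kk <- matrix(0L, m, K)
      for (j in seq_along(thetas)) {
        p <- .genewise_pop_p(h_tot[, j], thetas[[j]], direction)
        ok <- !is.na(p)
        acc[ok] <- acc[ok] - 2 * log(p[ok])
        kk <- kk + ok
      }
      acc[kk == 0] <- NA_real_
      fcs[, , r] <- acc
    }
  })
  structure(list(fcs = fcs, mode = mode, R = R, seed = seed,
                 direction = direction, n_populations = length(thetas)),
            class = "null_ensemble")
}

#' Empirical p-value against a null ensemble
#'
#' Uses the add-one Monte-Carlo estimator
#' `p = (1 + #\{null >= observed\}) / (1 + N)`, which never returns 0; ties
#' count toward the null. In `max_statistic` mode the null pool is each
#' replicate's genome-wide maximum, giving family-wise control.
#'
#' @param observed Numeric vector of observed `F_CS` values.
#' @param ensemble A `null_ensemble`.
#' @param mode Optional mode check; errors if it disagrees with the
#'   ensemble's mode.
#' @return Numeric vector of empirical p-values in `[1/(N+1), 1]`.
#' @export
empirical_p <- function(observed, ensemble, mode = NULL) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (!is.null(mode) && !identical(mode, ensemble$mode))
    stop("mode mismatch: ensemble was built in '", ensemble$mode, "' mode")
  pool <- if (ensemble$mode == "per_gene") {
    as.vector(ensemble$fcs)
  } else {
    apply(ensemble$fcs, 3, max, na.rm = TRUE)
  }
  pool <- sort(pool[is.finite(pool)])
  N <- length(pool)
  if (!N) stop("empty null pool")
  n_below <- findInterval(observed, pool, left.open = TRUE)  # #{pool < obs}
  (1 + (N - n_below)) / (1 + N)
}

#' Power of the cross-population combined test by simulation
#'
#' For each sample size `n`, simulates `R` replicate cohorts in which one
#' focal gene has its target-ancestry fraction raised to `f_target` while
#' the remaining genes follow each population's genome-wide fractions, and
#' reports the fraction of replicates whose focal-gene combined chi-square
#' p-value falls below `alpha`.
#'
#' @param f_target Focal-gene expected fraction of the target ancestry.
#' @param thetas List of per-population ancestry fraction vectors.
#' @param n_grid Diploid sample sizes to evaluate.
#' @param R Replicates per sample size.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @param target Target ancestry index (default 1).
#' @param m_genes Genes per replicate (focal gene plus background).
#' @return data.frame with `n` and `power`.
#' @export
power_analysis <- function(f_target, thetas, n_grid, R = 50, alpha = 1e-4,
                           seed = 1, target = 1L, m_genes = 100L) {
  stopifnot(all(n_grid >= 1), alpha > 0, alpha < 1, R >= 1)
  thetas_f <- lapply(thetas, .inject_theta, target_idx = target,
                     f_target = f_target)
  power <- with_seed(seed, vapply(n_grid, function(n) {
    h <- 2L * as.integer(n)
    hits <- vapply(seq_len(R), function(r) {
      pvec <- vapply(seq_along(thetas), function(j) {
        counts <- rbind(
          .rmultinom_rows(h, thetas_f[[j]]),
          .rmultinom_rows(rep(h, m_genes - 1L), thetas[[j]]))
        f <- counts / h
        mu <- colMeans(f)
        sigma <- apply(f, 2, stats::sd)
        z <- (f[1, target] - mu[target]) / sigma[target]
        max(stats::pnorm(z, lower.tail = FALSE), 1e-320)
      }, 0)
      fisher_score(pvec)$p_chi2 < alpha
    }, NA)
    mean(hits)
  }, 0))
  data.frame(n = n_grid, power = power)
}

#' Wright-Fisher simulation configuration
#'
#' @param N Diploid population size.
#' @param generations Generations since admixture (`g >= 0`).
#' @param theta Named founding ancestry proportions (sum to 1).
#' @param chrom Chromosome name.
#' @param chrom_length_bp Chromosome length in bp.
#' @param cM_per_Mb Constant recombination rate (ignored if `map` given).
#' @param map Optional [recomb_map()] (piecewise rates).
#' @param sample_size Diploids sampled (without replacement) for output.
#' @param population Output population label.
#' @param seed Integer seed.
#' @return Object of class `wf_config`.
#' @export
wf_config <- function(N = 100, generations = 10,
                      theta = c(AFR = 0.25, EUR = 0.5, NAT = 0.25),
                      chrom = "chr6", chrom_length_bp = 1e8, cM_per_Mb = 1,
                      map = NULL, sample_size = N, population = "WF",
                      seed = 1) {
  stopifnot(N >= 2, generations >= 0, abs(sum(theta) - 1) < 1e-9,
            all(theta >= 0), chrom_length_bp > 0)
  if (sample_size > N) stop("sample_size exceeds the population size N")
  if (is.null(names(theta))) stop("theta must be named by ancestry")
  if (is.null(map)) map <- recomb_map(chrom_length_bp, cM_per_Mb)
  structure(list(N = as.integer(N), generations = as.integer(generations),
                 theta = theta, chrom = chrom,
                 chrom_length_bp = chrom_length_bp, map = map,
                 sample_size = as.integer(sample_size),
                 population = population, seed = as.integer(seed)),
            class = "wf_config")
}

# One gamete: Poisson(map length in Morgans) crossovers at genetic positions
# iid uniform, alternating between the parent's two haplotypes from a
# random starting haplotype.
.gamete <- function(hA, hB, L_cM, map, span) {
  ncx <- stats::rpois(1, L_cM / 100)
  first <- sample.int(2L, 1L)
  if (ncx == 0) return(if (first == 1L) hA else hB)
  cx <- sort(unique(round(cM_to_bp(map, stats::runif(ncx) * L_cM))))
  cx <- cx[cx > span[1] & cx < span[2]]
  if (!length(cx)) return(if (first == 1L) hA else hB)
  .recombine(hA, hB, cx, first, span)
}

.recombine <- function(hA, hB, cx, first, span) {
  bounds <- c(cx, span[2])
  nseg <- length(bounds)
  ends <- vector("list", nseg)
  anc <- vector("list", nseg)
  lo <- span[1]
  src <- first
  stA <- .hap_starts(hA, span)
  stB <- .hap_starts(hB, span)
  for (i in seq_len(nseg)) {
    b <- bounds[i]
    if (src == 1L) { h <- hA; st <- stA } else { h <- hB; st <- stB }
    j1 <- findInterval(lo, st)
    j2 <- findInterval(b - 1, st)
    e <- h$ends[j1:j2]
    e[length(e)] <- b
    ends[[i]] <- e
    anc[[i]] <- h$anc[j1:j2]
    lo <- b
    src <- 3L - src
  }
  .merge_hap(list(ends = unlist(ends), anc = unlist(anc)))
}

#' Wright-Fisher forward simulation of an admixing population
#'
#' Generation 0 consists of `N` single-ancestry diploids with ancestry
#' composition given by largest-remainder rounding of `N * theta`. Each
#' subsequent generation of `N` offspring draws two parents uniformly with
#' replacement (monoecious random mating, selfing allowed); each parent
#' transmits one recombinant gamete. After `generations` generations a
#' uniform sample of `sample_size` diploids is returned as a panel. There
#' is no mutation and no selection; ancestry-fraction dynamics are pure
#' drift.
#'
#' @param cfg A [wf_config()].
#' @param check Validate the tract tiling of every haplotype at every
#'   generation (slower; used by tests).
#' @return A [haplotype_panel()].
#' @export
wright_fisher_sim <- function(cfg, check = FALSE) {
  stopifnot(inherits(cfg, "wf_config"))
  span <- c(0, cfg$chrom_length_bp)
  L_cM <- map_length_cM(cfg$map)
  K <- length(cfg$theta)
  founders <- largest_remainder(cfg$N, cfg$theta)
  anc0 <- rep(seq_len(K) - 1L, founders)
  pop <- vector("list", 2L * cfg$N)
  for (i in seq_len(cfg$N)) {
    h <- list(ends = span[2], anc = anc0[i])
    pop[[2L * i - 1L]] <- h
    pop[[2L * i]] <- h
  }
  with_seed(cfg$seed, {
    for (gen in seq_len(cfg$generations)) {
      nxt <- vector("list", 2L * cfg$N)
      par1 <- sample.int(cfg$N, cfg$N, replace = TRUE)
      par2 <- sample.int(cfg$N, cfg$N, replace = TRUE)
      for (i in seq_len(cfg$N)) {
        p1 <- par1[i]; p2 <- par2[i]
        nxt[[2L * i - 1L]] <- .gamete(pop[[2L * p1 - 1L]], pop[[2L * p1]],
                                      L_cM, cfg$map, span)
        nxt[[2L * i]] <- .gamete(pop[[2L * p2 - 1L]], pop[[2L * p2]],
                                 L_cM, cfg$map, span)
      }
      pop <- nxt
      if (check) {
        for (h in pop) .validate_hap(h, span, K, what = paste0("gen ", gen))
      }
    }
    idx <- sort(sample.int(cfg$N, cfg$sample_size))
    haps <- vector("list", 2L * cfg$sample_size)
    for (i in seq_along(idx)) {
      haps[[2L * i - 1L]] <- pop[[2L * idx[i] - 1L]]
      haps[[2L * i]] <- pop[[2L * idx[i]]]
    }
    haplotype_panel(cfg$population,
                    sprintf("%s_%04d", cfg$population,
                            seq_len(cfg$sample_size)),
                    haps, ancestry_palette(names(cfg$theta)),
                    cfg$chrom, span, cfg$map)
  })
}

#' Chromosome-scale Wright-Fisher null ensemble
#'
#' Per replicate, simulates one Wright-Fisher population per configured
#' population, runs the ancestry-enrichment scan and Fisher combination on
#' the given genes, and stores the combined scores. Unlike the gene-wise
#' null, this route carries linkage between neighboring genes and drift
#' noise in the realized ancestry fractions.
#'
#' @param cfgs Named list of [wf_config()]s, one per population.
#' @param genes Gene-model data.frame on the simulated chromosome.
#' @param R Number of replicates.
#' @param seed Integer seed (per-replicate, per-population seeds are
#'   derived from it).
#' @param direction `"enrich"` or `"deplete"`.
#' @param mode `"per_gene"` or `"max_statistic"`.
#' @return A `null_ensemble` (genes outside a replicate's retained
#'   universe are `NA`).
#' @export
chromosome_null <- function(cfgs, genes, R, seed = 1,
                            direction = c("enrich", "deplete"),
                            mode = c("per_gene", "max_statistic")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  stopifnot(R >= 1, length(cfgs) >= 1)
  labels <- names(cfgs[[1]]$theta)
  m <- nrow(genes)
  fcs <- array(NA_real_, dim = c(m, length(labels), R),
               dimnames = list(genes$name, labels, NULL))
  for (r in seq_len(R)) {
    tables <- lapply(names(cfgs), function(p) {
      cfg <- cfgs[[p]]
      cfg$seed <- derive_seed(seed, paste0("wfnull:", r, ":", p))
      scan_panel(wright_fisher_sim(cfg), genes)
    })
    comb <- suppressWarnings(fisher_combine(tables, direction = direction))
    idx <- cbind(match(comb$gene, genes$name), match(comb$ancestry, labels))
    slab <- fcs[, , r]
    slab[idx] <- comb$F_CS
    fcs[, , r] <- slab
  }
  structure(list(fcs = fcs, mode = mode, R = R, seed = seed,
                 direction = direction, n_populations = length(cfgs)),
            class = "null_ensemble")
}
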