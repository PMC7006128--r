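# Polygenic ancestry enrichment (PAE).
#
# PAE for a trait gene set is the sum of the gene-level enrichment z-scores
# of its genes, PAE = sum(z_anc). Significance comes from size-matched
# permutation nulls: 10,000 random gene sets of the same size drawn without
# replacement from the retained gene universe give the permutation mean and
# SD, and z_PAE = (PAE_obs - mu_PAE) / sigma_PAE is tested two-sided
# against the normal distribution (the empirical permutation rank p is
# also reported). Traits significant with the same ancestry and direction
# in multiple populations form the cross-population consensus.

# Retained genes with defined z for one ancestry: the permutation universe.
.universe_z <- function(table, ancestry) {
  rows <- table$ancestry == ancestry & table$retained & !is.na(table$z_anc)
  stats::setNames(table$z_anc[rows], table$gene[rows])
}

#' Observed polygenic ancestry enrichment for one trait
#'
#' Sums `z_anc` over the trait's genes that are present in the retained
#' universe with a defined score; absent genes are dropped and counted.
#'
#' @param table A `gene_score_table` (one population).
#' @param trait A [trait_set()].
#' @param ancestry Ancestry label.
#' @return List with `pae`, `n_used`, `n_missing`.
#' @export
compute_pae <- function(table, trait, ancestry) {
  uz <- .universe_z(table, ancestry)
  g <- intersect(trait$genes, names(uz))
  if (!length(g)) {
    warning("trait '", trait$trait, "' has no usable genes; skipped")
    return(list(pae = NA_real_, n_used = 0L,
                n_missing = length(trait$genes)))
  }
  list(pae = sum(uz[g]), n_used = length(g),
       n_missing = length(trait$genes) - length(g))
}

#' Size-matched permutation null for PAE
#'
#' Each permutation draws `set_size` genes uniformly without replacement
#' from the retained universe of the given ancestry and sums their `z_anc`.
#'
#' @param table A `gene_score_table`.
#' @param set_size Genes per permuted set.
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Integer seed.
#' @param ancestry Ancestry label.
#' @return List with `mu`, `sigma`, `null` (the permutation sums),
#'   `set_size`, `n_perm`, `degenerate` (TRUE when `sigma` is 0 or
#'   undefined, flagged with a warning).
#' @export
permutation_null <- function(table, set_size, n_perm = 10000, seed = 1,
                             ancestry) {
  uz <- unname(.universe_z(table, ancestry))
  m <- length(uz)
  if (set_size > m)
    stop("set_size (", set_size, ") exceeds the universe size (", m, ")")
  if (set_size < 1) stop("set_size must be >= 1")
  sums <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) sum(uz[sample.int(m, set_size)]), 0)
  })
  mu <- mean(sums)
  sigma <- stats::sd(sums)
  degenerate <- !is.finite(sigma) || sigma == 0
  if (degenerate)
    warning("degenerate permutation null (sigma_PAE undefined or 0)")
  list(mu = mu, sigma = sigma, null = sums, set_size = set_size,
       n_perm = n_perm, degenerate = degenerate)
}

#' Polygenic ancestry enrichment scan
#'
#' Computes PAE for every trait x ancestry x population, its size-matched
#' permutation null, `z_PAE`, two-sided normal p, empirical rank p, and
#' Benjamini-Hochberg q-values within each (population, ancestry) family.
#' Permutation nulls are cached by set size within each family, and their
#' seeds are derived from the family and size so results do not depend on
#' trait order.
#'
#' @param tables List of `gene_score_table`s, one per population.
#' @param traits List of [trait_set()]s.
#' @param n_perm Permutations per null (default 10,000).
#' @param seed Integer seed.
#' @param q_threshold FDR threshold (default 0.05).
#' @return data.frame: `trait`, `population`, `ancestry`, `n_genes_used`,
#'   `pae_obs`, `mu_pae`, `sigma_pae`, `z_pae`, `p`, `p_rank`, `q`,
#'   `direction`.
#' @export
pae_scan <- function(tables, traits, n_perm = 10000, seed = 1,
                     q_threshold = 0.05) {
  labels <- attr(tables[[1]], "labels")
  rows <- list()
  for (tb in tables) {
    popname <- attr(tb, "population")
    for (anc in labels) {
      uz <- .universe_z(tb, anc)
      if (!length(uz)) next
      cache <- new.env(parent = emptyenv())
      for (ts in traits) {
        obs <- suppressWarnings(compute_pae(tb, ts, anc))
        if (obs$n_used == 0 || obs$n_used > length(uz)) {
          rows[[length(rows) + 1]] <- data.frame(
            trait = ts$trait, population = popname, ancestry = anc,
            n_genes_used = obs$n_used, pae_obs = NA_real_,
            mu_pae = NA_real_, sigma_pae = NA_real_, z_pae = NA_real_,
            p = NA_real_, p_rank = NA_real_, q = NA_real_,
            direction = "none", stringsAsFactors = FALSE)
          next
        }
        key <- as.character(obs$n_used)
        if (is.null(cache[[key]])) {
          cache[[key]] <- suppressWarnings(permutation_null(
            tb, obs$n_used, n_perm = n_perm,
            seed = derive_seed(seed, paste("pae", popname, anc, key)),
            ancestry = anc))
        }
        nul <- cache[[key]]
        if (nul$degenerate) {
          z <- NA_real_; p <- NA_real_; pr <- NA_real_
        } else {
          z <- (obs$pae - nul$mu) / nul$sigma
          p <- 2 * stats::pnorm(-abs(z))
          pr <- (1 + sum(abs(nul$null - nul$mu) >=
                           abs(obs$pae - nul$mu))) / (1 + nul$n_perm)
        }
        rows[[length(rows) + 1]] <- data.frame(
          trait = ts$trait, population = popname, ancestry = anc,
          n_genes_used = obs$n_used, pae_obs = obs$pae,
          mu_pae = nul$mu, sigma_pae = nul$sigma, z_pae = z,
          p = p, p_rank = pr,
          q = NA_real_,
          direction = if (is.na(z) || z == 0) "none"
                      else if (z > 0) "enrich" else "deplete",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  # BH within each (population, ancestry) family
  for (fam in split(seq_len(nrow(out)),
                    paste(out$population, out$ancestry))) {
    ok <- fam[!is.na(out$p[fam])]
    if (length(ok)) out$q[ok] <- bh_fdr(out$p[ok], q_threshold)$q
  }
  structure(out, class = c("pae_result", "data.frame"),
            q_threshold = q_threshold, n_perm = n_perm, seed = seed)
}

#' Cross-population trait consensus
#'
#' Traits significant (`q < q_threshold`) for the same ancestry with the
#' same direction in at least `min_pops` populations.
#'
#' @param results A [pae_scan()] result.
#' @param min_pops Minimum number of agreeing populations (default 2).
#' @param q_threshold FDR threshold (defaults to the scan's).
#' @return data.frame: `trait`, `ancestry`, `direction`, `n_pops`,
#'   `populations`, `z_pae_values`, `mean_z_pae`.
#' @export
cross_population_traits <- function(results, min_pops = 2,
                                    q_threshold = NULL) {
  if (is.null(q_threshold))
    q_threshold <- attr(results, "q_threshold") %||% 0.05
  sig <- results[!is.na(results$q) & results$q < q_threshold &
                   results$direction != "none", , drop = FALSE]
  if (!nrow(sig)) {
    return(data.frame(trait = character(), ancestry = character(),
                      direction = character(), n_pops = integer(),
                      populations = character(), z_pae_values = character(),
                      mean_z_pae = numeric(), stringsAsFactors = FALSE))
  }
  keys <- paste(sig$trait, sig$ancestry, sig$direction, sep = "\r")
  out <- lapply(split(seq_len(nrow(sig)), keys), function(i) {
    s <- sig[i, , drop = FALSE]
    pops <- unique(s$population)
    if (length(pops) < min_pops) return(NULL)
    data.frame(trait = s$trait[1], ancestry = s$ancestry[1],
               direction = s$direction[1], n_pops = length(pops),
               populations = paste(s$population, collapse = ","),
               z_pae_values = paste(sprintf("%.3f", s$z_pae),
                                    collapse = ","),
               mean_z_pae = mean(s$z_pae), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) {
    return(data.frame(trait = character(), ancestry = character(),
                      direction = character(), n_pops = integer(),
                      populations = character(), z_pae_values = character(),
                      mean_z_pae = numeric(), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out[order(-out$n_pops, -abs(out$mean_z_pae)), , drop = FALSE]
}

#' Physical-distance pruning of a trait gene set
#'
#' Greedy left-to-right retention within each chromosome: a gene is dropped
#' when it starts within `min_gap_bp` of the previously retained gene's
#' end. This is a genotype-free proxy for LD pruning of gene sets; trait
#' genes without coordinates are retained with a warning.
#'
#' @param trait A [trait_set()].
#' @param genes Gene-model data.frame providing coordinates.
#' @param min_gap_bp Minimum start-to-previous-end gap (default 250 kb).
#' @return A pruned [trait_set()].
#' @export
distance_prune_geneset <- function(trait, genes, min_gap_bp = 250000) {
  idx <- match(trait$genes, genes$name)
  nocoord <- trait$genes[is.na(idx)]
  if (length(nocoord))
    warning("genes without coordinates retained: ",
            paste(nocoord, collapse = ","))
  g <- genes[idx[!is.na(idx)], , drop = FALSE]
  kept <- character(0)
  for (chr in unique(g$chrom)) {
    gc <- g[g$chrom == chr, , drop = FALSE]
    gc <- gc[order(gc$start), , drop = FALSE]
    prev_end <- -Inf
    for (i in seq_len(nrow(gc))) {
      if (gc$start[i] - prev_end >= min_gap_bp) {
        kept <- c(kept, gc$name[i])
        prev_end <- gc$end[i]
      }
    }
  }
  trait_set(trait$trait, trait$description,
            c(trait$genes[trait$genes %in% kept], nocoord))
}
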