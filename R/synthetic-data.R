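# Synthetic local-ancestry cohorts with known ground truth.
#
# The generator follows the classic pulse-admixture approximation: along a
# haplotype, tract breakpoints form a Poisson process of rate g per Morgan
# (g generations since admixture) on the genetic map, and tract ancestries
# are drawn iid from the population's genome-wide ancestry fractions theta.
# Loci with injected ancestry enrichment reweight the tract ancestry
# probabilities inside chosen intervals so the expected local fraction of a
# target ancestry equals f_target; injections never change breakpoint
# density, which isolates the enrichment signal the downstream scan must
# detect. Tracts are independently relabelled UNASSIGNED with probability u,
# emulating the confidence filtering applied to real local-ancestry calls.

#' Cohort configuration for the synthetic-data generator
#'
#' @param populations Named list; each element `list(theta = , n = )` with
#'   `theta` a named numeric vector of ancestry fractions (same names and
#'   order across populations, summing to 1) and `n` the diploid sample
#'   count. Defaults to four admixed populations with a shared African
#'   fraction of 0.25 and distinct European/Native American profiles.
#' @param g Generations since admixture (tract breakpoint rate per Morgan).
#' @param chrom Chromosome name.
#' @param chrom_length_bp Chromosome length in bp.
#' @param cM_per_Mb Constant recombination rate.
#' @param gene_count,gene_width Number and width (bp) of the evenly spaced
#'   synthetic gene models.
#' @param unassigned_rate Probability `u` that a tract is relabelled
#'   UNASSIGNED (sub-confidence call).
#' @param injections List of `list(start =, end =, ancestry =, f_target =)`
#'   ancestry-enrichment injections (bp interval, target ancestry label,
#'   target expected local fraction in (0,1)).
#' @param seed Integer seed; all generated objects derive from it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(
    populations = list(
      CLM_like = list(theta = c(AFR = 0.25, EUR = 0.55, NAT = 0.20), n = 100L),
      MXL_like = list(theta = c(AFR = 0.25, EUR = 0.40, NAT = 0.35), n = 100L),
      PEL_like = list(theta = c(AFR = 0.25, EUR = 0.30, NAT = 0.45), n = 100L),
      PUR_like = list(theta = c(AFR = 0.25, EUR = 0.65, NAT = 0.10), n = 100L)),
    g = 10, chrom = "genome", chrom_length_bp = 2e9, cM_per_Mb = 1.3,
    gene_count = 200L, gene_width = 1e5, unassigned_rate = 0.02,
    injections = list(), seed = 1L) {
  stopifnot(length(populations) >= 1, g > 0, chrom_length_bp > 0,
            gene_count >= 1, gene_width > 0,
            unassigned_rate >= 0, unassigned_rate < 1)
  labels <- names(populations[[1]]$theta)
  if (is.null(labels)) stop("population theta vectors must be named")
  for (p in names(populations)) {
    th <- populations[[p]]$theta
    if (!identical(names(th), labels))
      stop("all populations must share the same ancestry labels in order")
    if (abs(sum(th) - 1) > 1e-12)
      stop("theta for population '", p, "' must sum to 1")
    if (any(th < 0)) stop("theta components must be non-negative")
    if (is.null(populations[[p]]$n) || populations[[p]]$n < 1)
      stop("population '", p, "' needs n >= 1 diploid samples")
  }
  if (gene_count * gene_width > chrom_length_bp)
    stop("gene_count * gene_width exceeds the chromosome length")
  palette <- ancestry_palette(labels)
  for (inj in injections) {
    if (inj$start < 0 || inj$end > chrom_length_bp || inj$start >= inj$end)
      stop("injection interval outside the chromosome")
    if (!(inj$ancestry %in% labels)) stop("unknown injection ancestry")
    if (inj$f_target <= 0 || inj$f_target >= 1)
      stop("injection f_target must lie in (0,1)")
  }
  structure(
    list(populations = populations, g = g, chrom = chrom,
         chrom_length_bp = chrom_length_bp, cM_per_Mb = cM_per_Mb,
         gene_count = as.integer(gene_count), gene_width = gene_width,
         unassigned_rate = unassigned_rate, injections = injections,
         palette = palette, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Demo cohort configuration: one injected enrichment locus
#'
#' A single-chromosome cohort (100 Mb at 1 cM/Mb, 200 genes) with one 5-Mb
#' interval of injected African enrichment (local target fraction 0.45
#' against a genome-wide background of 0.25 in every population), mimicking
#' a strongly selected MHC-like region shared across admixed populations.
#'
#' @param seed Integer seed.
#' @return A [cohort_config()].
#' @export
demo_cohort_config <- function(seed = 1L) {
  cohort_config(
    chrom = "chr6", chrom_length_bp = 1e8, cM_per_Mb = 1,
    gene_count = 200L, gene_width = 1e5, unassigned_rate = 0.02,
    injections = list(list(start = 4.0e7, end = 4.5e7,
                           ancestry = "AFR", f_target = 0.45)),
    seed = seed)
}

# Reweighted tract ancestry probabilities inside an injection interval:
# target gets f_target, the rest keep their relative proportions.
.inject_theta <- function(theta, target_idx, f_target) {
  out <- theta * (1 - f_target) / (1 - theta[target_idx])
  out[target_idx] <- f_target
  out
}

#' Generate a synthetic local-ancestry panel for one population
#'
#' @param cfg A [cohort_config()].
#' @param population Population label (a name of `cfg$populations`).
#' @param merge Merge adjacent equal-ancestry tracts (canonical form,
#'   default). `merge = FALSE` keeps the raw Poisson tract draws, which is
#'   what tract-length diagnostics should use.
#' @return A [haplotype_panel()].
#' @export
generate_panel <- function(cfg, population, merge = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"))
  pop <- cfg$populations[[population]]
  if (is.null(pop)) stop("unknown population: ", population)
  theta <- pop$theta
  K <- cfg$palette$K
  n <- pop$n
  map <- recomb_map(cfg$chrom_length_bp, cfg$cM_per_Mb)
  L_cM <- map_length_cM(map)
  lambda <- cfg$g * L_cM / 100
  L <- cfg$chrom_length_bp

  inj <- cfg$injections
  inj_bounds <- unlist(lapply(inj, function(x) c(x$start, x$end)))
  inj_bounds <- inj_bounds[inj_bounds > 0 & inj_bounds < L]
  inj_theta <- lapply(inj, function(x) {
    .inject_theta(theta, match(x$ancestry, cfg$palette$labels), x$f_target)
  })

  haps <- with_seed(derive_seed(cfg$seed, paste0("panel:", population)), {
    lapply(seq_len(2 * n), function(i) {
      ncx <- stats::rpois(1, lambda)
      cx <- if (ncx > 0) {
        p <- round(cM_to_bp(map, stats::runif(ncx) * L_cM))
        unique(p[p > 0 & p < L])
      } else numeric(0)
      ends <- sort(unique(c(cx, inj_bounds, L)))
      mids <- (c(0, ends[-length(ends)]) + ends) / 2
      anc <- integer(length(ends))
      assigned <- rep(FALSE, length(ends))
      for (j in seq_along(inj)) {
        inside <- !assigned & mids >= inj[[j]]$start & mids < inj[[j]]$end
        if (any(inside)) {
          anc[inside] <- sample.int(K, sum(inside), replace = TRUE,
                                    prob = inj_theta[[j]]) - 1L
          assigned <- assigned | inside
        }
      }
      if (any(!assigned)) {
        anc[!assigned] <- sample.int(K, sum(!assigned), replace = TRUE,
                                     prob = theta) - 1L
      }
      if (cfg$unassigned_rate > 0) {
        drop <- stats::runif(length(anc)) < cfg$unassigned_rate
        anc[drop] <- UNASSIGNED
      }
      h <- list(ends = ends, anc = anc)
      if (merge) .merge_hap(h) else h
    })
  })
  panel <- structure(
    list(population = population,
         samples = sprintf("%s_%04d", population, seq_len(n)),
         haplotypes = haps, palette = cfg$palette,
         chrom = cfg$chrom, span = c(0, L), map = map),
    class = "haplotype_panel")
  names(panel$haplotypes) <- paste0(rep(panel$samples, each = 2), ".",
                                    c(0L, 1L))
  validate_haplotype_panel(panel)
  panel
}

#' Generate evenly spaced non-overlapping gene models
#'
#' @param cfg A [cohort_config()].
#' @return data.frame (`chrom`, `start`, `end`, `name`) with
#'   `cfg$gene_count` disjoint sorted intervals of width `cfg$gene_width`.
#' @export
generate_genes <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  m <- cfg$gene_count
  spacing <- cfg$chrom_length_bp / m
  offset <- floor((spacing - cfg$gene_width) / 2)
  start <- floor((seq_len(m) - 1) * spacing) + offset
  data.frame(chrom = cfg$chrom, start = start,
             end = start + cfg$gene_width,
             name = sprintf("G%03d", seq_len(m)),
             stringsAsFactors = FALSE)
}

#' Generate random trait gene sets (plus an optional enriched set)
#'
#' Random sets are sampled uniformly without replacement from the gene
#' models. They act as negative controls for the polygenic test, so when
#' the configuration has injections the random pool excludes genes
#' intersecting the injected intervals (otherwise a "null" trait could
#' carry planted signal). If `enriched_trait` is given, that set is built
#' from genes intersecting the injection intervals, so it carries the
#' injected polygenic signal by construction.
#'
#' @param cfg A [cohort_config()].
#' @param genes Gene models from [generate_genes()].
#' @param n_traits Number of random trait sets.
#' @param set_size Genes per set (must not exceed the gene count).
#' @param enriched_trait Optional name for the injected-signal trait set.
#' @return Named list of [trait_set()] objects.
#' @export
generate_trait_sets <- function(cfg, genes, n_traits, set_size,
                                enriched_trait = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  m <- nrow(genes)
  if (set_size > m) stop("set_size exceeds the number of genes")
  hit <- rep(FALSE, m)
  for (inj in cfg$injections) {
    hit <- hit | (genes$start < inj$end & genes$end > inj$start)
  }
  null_pool <- genes$name[!hit]
  if (set_size > length(null_pool))
    stop("set_size exceeds the number of non-injected genes")
  out <- with_seed(derive_seed(cfg$seed, "traits"), {
    sets <- lapply(seq_len(n_traits), function(i) {
      trait_set(sprintf("trait_%02d", i), "random gene set",
                sample(null_pool, set_size))
    })
    if (!is.null(enriched_trait)) {
      if (!length(cfg$injections))
        stop("enriched_trait requested but the config has no injections")
      pool <- genes$name[hit]
      if (!length(pool)) stop("no genes intersect the injection intervals")
      chosen <- if (length(pool) > set_size) sample(pool, set_size) else pool
      sets <- c(sets, list(trait_set(enriched_trait,
                                     "genes at injected enrichment loci",
                                     chosen)))
    }
    sets
  })
  names(out) <- vapply(out, `[[`, "", "trait")
  out
}

#' Generate a full synthetic cohort in memory
#'
#' @param cfg A [cohort_config()].
#' @param n_traits,set_size,enriched_trait Passed to
#'   [generate_trait_sets()]; the enriched set is only built when the
#'   config has injections.
#' @return List with `panels` (one [haplotype_panel()] per population),
#'   `genes`, `traits`, `truth` (injection ground-truth data.frame), `cfg`.
#' @export
generate_cohort <- function(cfg, n_traits = 20, set_size = 10,
                            enriched_trait = if (length(cfg$injections))
                              "injected_trait" else NULL) {
  panels <- lapply(names(cfg$populations), function(p) generate_panel(cfg, p))
  names(panels) <- names(cfg$populations)
  genes <- generate_genes(cfg)
  traits <- generate_trait_sets(cfg, genes, n_traits, set_size,
                                enriched_trait)
  truth <- if (length(cfg$injections)) {
    do.call(rbind, lapply(cfg$injections, function(x) {
      data.frame(chrom = cfg$chrom, start = x$start, end = x$end,
                 ancestry = x$ancestry, f_target = x$f_target)
    }))
  } else {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               ancestry = character(), f_target = numeric())
  }
  list(panels = panels, genes = genes, traits = traits, truth = truth,
       cfg = cfg)
}

#' Write a synthetic cohort to disk
#'
#' Emits one msp file per population, a BED4 gene-model file, a GMT trait
#' file, a ground-truth TSV of the injections, and a theta TSV of the
#' configured ancestry fractions.
#'
#' @param cfg A [cohort_config()].
#' @param dir Output directory (created if needed).
#' @param ... Passed to [generate_cohort()].
#' @return Named list of written paths (and the in-memory cohort as
#'   attribute `"cohort"`), invisibly.
#' @export
write_cohort <- function(cfg, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  co <- generate_cohort(cfg, ...)
  msp <- vapply(names(co$panels), function(p) {
    path <- file.path(dir, paste0(p, ".msp.tsv"))
    write_msp(co$panels[[p]], path)
    path
  }, "")
  bed <- file.path(dir, "genes.bed")
  utils::write.table(co$genes, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  gmt <- file.path(dir, "traits.gmt")
  write_gmt(co$traits, gmt)
  truth <- file.path(dir, "truth.tsv")
  write_result_table(co$truth, truth)
  theta <- file.path(dir, "theta.tsv")
  th <- do.call(rbind, lapply(names(cfg$populations), function(p) {
    data.frame(population = p, ancestry = names(cfg$populations[[p]]$theta),
               theta = as.numeric(cfg$populations[[p]]$theta),
               n = cfg$populations[[p]]$n)
  }))
  write_result_table(th, theta)
  out <- list(msp = msp, bed = bed, gmt = gmt, truth = truth, theta = theta)
  attr(out, "cohort") <- co
  invisible(out)
}
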