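# End-to-end orchestration of the screen: scan -> universe -> Fisher
# combination (+FDR) -> optional admixture null -> polygenic PAE ->
# cross-population consensus -> selection-coefficient fit on the top hit.

#' Pipeline run configuration
#'
#' @param msp Named character vector of msp file paths, one per population
#'   (names are the population labels).
#' @param bed Path to the BED4 gene models.
#' @param gmt Optional path to the GMT trait sets (PAE stage skipped when
#'   `NULL`).
#' @param score_track Optional score-track path for the |iHS|-style
#'   overlay.
#' @param score_dialect Track dialect for [read_score_track()].
#' @param ihs_threshold Overlay flag threshold (default 2.5).
#' @param flank_bp Overlay flank in bp.
#' @param q_threshold FDR threshold (default 0.05).
#' @param null_mode `"none"`, `"genewise"` or `"wf"` admixture null for
#'   empirical p-values.
#' @param null_replicates Replicates for the null ensemble.
#' @param pae_n_perm PAE permutations (default 10,000).
#' @param min_pops Populations required for trait consensus (default 2).
#' @param selection_t Generations assumed in the selection fit (default 20).
#' @param selection_favored Favored ancestry label for the selection fit.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param out_dir Output directory for result tables and the manifest.
#' @return Object of class `run_config`.
#' @export
run_config <- function(msp, bed, gmt = NULL, score_track = NULL,
                       score_dialect = "generic_tsv", ihs_threshold = 2.5,
                       flank_bp = 0, q_threshold = 0.05,
                       null_mode = c("none", "genewise", "wf"),
                       null_replicates = 100, pae_n_perm = 10000,
                       min_pops = 2, selection_t = 20,
                       selection_favored = "AFR", seed = 1,
                       out_dir = tempfile("admixscan_")) {
  null_mode <- match.arg(null_mode)
  if (is.null(names(msp)) || any(!nzchar(names(msp))))
    stop("msp paths must be named by population")
  structure(list(msp = msp, bed = bed, gmt = gmt,
                 score_track = score_track, score_dialect = score_dialect,
                 ihs_threshold = ihs_threshold, flank_bp = flank_bp,
                 q_threshold = q_threshold, null_mode = null_mode,
                 null_replicates = null_replicates,
                 pae_n_perm = pae_n_perm, min_pops = min_pops,
                 selection_t = selection_t,
                 selection_favored = selection_favored,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

.log_stage <- function(manifest, stage, ...) {
  msg <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  message(msg)
  c(manifest, msg)
}

#' Run the full admixture-enabled selection screen
#'
#' Executes every stage configured in `cfg`, writes one TSV per stage plus
#' a manifest under `cfg$out_dir`, and returns the stage results. With a
#' single population, the cross-population stages are skipped with an
#' explicit notice; the per-population scan is still emitted. Identical
#' configuration and seed give identical outputs.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `tables`, `universe`, `combined`
#'   (enrich/deplete), `pae`, `consensus`, `selection`, `overlay`,
#'   `manifest`.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  manifest <- .log_stage(manifest, "config",
                         "seed=", cfg$seed, " populations=",
                         paste(names(cfg$msp), collapse = ","))

  genes <- read_bed(cfg$bed)
  panels <- lapply(names(cfg$msp), function(p) {
    read_msp(cfg$msp[[p]], population = p)
  })
  names(panels) <- names(cfg$msp)
  manifest <- .log_stage(manifest, "load", nrow(genes), " genes, ",
                         length(panels), " population panel(s)")

  tables <- lapply(panels, scan_panel, genes = genes)
  for (p in names(tables)) {
    write_result_table(as.data.frame(tables[[p]]),
                       file.path(cfg$out_dir, paste0("scores_", p, ".tsv")))
  }
  manifest <- .log_stage(manifest, "scan", "per-gene ancestry scores for ",
                         length(tables), " population(s)")

  universe <- NULL
  combined <- list()
  ensemble <- NULL
  if (length(tables) >= 2) {
    universe <- finalize_gene_universe(tables)
    manifest <- .log_stage(manifest, "universe", length(universe),
                           " genes retained in every population")
    for (dir in c("enrich", "deplete")) {
      combined[[dir]] <- fisher_combine(tables, universe, dir,
                                        cfg$q_threshold)
    }
    if (cfg$null_mode == "genewise") {
      h_tot <- vapply(tables, function(t) {
        t$h_tot[t$ancestry == t$ancestry[1]][match(universe, unique(t$gene))]
      }, numeric(length(universe)))
      thetas <- lapply(panels, panel_ancestry_fractions)
      ensemble <- genewise_null(h_tot, thetas, cfg$null_replicates,
                                derive_seed(cfg$seed, "genewise_null"))
      combined$enrich$p_empirical <- empirical_p(combined$enrich$F_CS,
                                                 ensemble)
      manifest <- .log_stage(manifest, "null", "genewise ensemble, R=",
                             cfg$null_replicates)
    } else if (cfg$null_mode == "wf") {
      cfgs <- lapply(names(panels), function(p) {
        th <- panel_ancestry_fractions(panels[[p]])
        wf_config(N = length(panels[[p]]$samples), generations = 10,
                  theta = th / sum(th),
                  chrom = panels[[p]]$chrom,
                  chrom_length_bp = diff(panels[[p]]$span),
                  map = panels[[p]]$map,
                  population = p)
      })
      names(cfgs) <- names(panels)
      ensemble <- chromosome_null(cfgs, genes, cfg$null_replicates,
                                  derive_seed(cfg$seed, "wf_null"))
      combined$enrich$p_empirical <- empirical_p(combined$enrich$F_CS,
                                                 ensemble)
      manifest <- .log_stage(manifest, "null", "Wright-Fisher ensemble, R=",
                             cfg$null_replicates)
    }
    for (dir in names(combined)) {
      write_result_table(as.data.frame(combined[[dir]]),
                         file.path(cfg$out_dir,
                                   paste0("combined_", dir, ".tsv")))
    }
    manifest <- .log_stage(
      manifest, "combine", "q<", cfg$q_threshold, ": ",
      sum(combined$enrich$reject, na.rm = TRUE), " enrich / ",
      sum(combined$deplete$reject, na.rm = TRUE), " deplete rows")
  } else {
    manifest <- .log_stage(manifest, "combine",
                           "skipped: needs >= 2 populations")
  }

  overlay <- NULL
  if (!is.null(cfg$score_track)) {
    track <- read_score_track(cfg$score_track, cfg$score_dialect)
    overlay <- overlay_scores(genes, track, cfg$ihs_threshold, cfg$flank_bp)
    write_result_table(overlay, file.path(cfg$out_dir, "overlay.tsv"))
    manifest <- .log_stage(manifest, "overlay",
                           sum(overlay$above_threshold),
                           " gene(s) above |score| >= ", cfg$ihs_threshold)
  }

  pae <- NULL
  consensus <- NULL
  if (!is.null(cfg$gmt)) {
    traits <- read_gmt(cfg$gmt)
    pae <- suppressWarnings(
      pae_scan(tables, traits, cfg$pae_n_perm,
               derive_seed(cfg$seed, "pae"), cfg$q_threshold))
    write_result_table(as.data.frame(pae),
                       file.path(cfg$out_dir, "pae.tsv"))
    manifest <- .log_stage(manifest, "pae", nrow(pae), " trait tests")
    if (length(tables) >= cfg$min_pops) {
      consensus <- cross_population_traits(pae, cfg$min_pops)
      write_result_table(consensus,
                         file.path(cfg$out_dir, "pae_consensus.tsv"))
      manifest <- .log_stage(manifest, "consensus", nrow(consensus),
                             " trait(s) in >= ", cfg$min_pops,
                             " population(s)")
    }
  }

  selection <- NULL
  if (length(combined) && !is.null(cfg$selection_favored)) {
    fav <- cfg$selection_favored
    rows <- combined$enrich[combined$enrich$ancestry == fav &
                              !is.na(combined$enrich$p_chi2), , drop = FALSE]
    if (nrow(rows)) {
      top_gene <- rows$gene[which.min(rows$p_chi2)]
      z_obs <- vapply(tables, function(t) {
        t$z_anc[t$gene == top_gene & t$ancestry == fav]
      }, 0)
      mu <- vapply(tables, function(t) attr(t, "mu_anc")[[fav]], 0)
      sigma <- vapply(tables, function(t) attr(t, "sigma_anc")[[fav]], 0)
      selection <- tryCatch(
        fit_populations(z_obs, mu, sigma, t = cfg$selection_t),
        error = function(e) {
          manifest <<- .log_stage(manifest, "selection",
                                  "fit failed: ", conditionMessage(e))
          NULL
        })
      if (!is.null(selection)) {
        tab <- selection$table
        tab$gene <- top_gene
        write_result_table(tab, file.path(cfg$out_dir, "selection_fit.tsv"))
        traj <- selection_trajectory(
          stats::setNames(c(mu[1], 1 - mu[1]), c(fav, "other"))[
            c(fav, "other")],
          fav, selection$mean_s, cfg$selection_t, mu[1], sigma[1])
        write_result_table(traj,
                           file.path(cfg$out_dir,
                                     "selection_trajectory.tsv"))
        manifest <- .log_stage(manifest, "selection", "top ", fav,
                               " gene ", top_gene, ": mean s_hat = ",
                               sprintf("%.4f", selection$mean_s))
      }
    }
  }

  manifest <- .log_stage(manifest, "done", "all configured stages completed")
  writeLines(manifest, file.path(cfg$out_dir, "manifest.txt"))
  invisible(list(tables = tables, universe = universe, combined = combined,
                 ensemble = ensemble, pae = pae, consensus = consensus,
                 selection = selection, overlay = overlay,
                 manifest = manifest))
}

#' Create the demonstration workspace
#'
#' Generates the four-population synthetic cohort with one injected
#' African-enrichment locus (an MHC-like region) and one enriched trait
#' set, writes it under `out_dir`, and returns a ready-to-run
#' [run_config()].
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param n_traits,set_size Random trait sets accompanying the injected
#'   one.
#' @return A [run_config()] pointing at the generated files.
#' @export
make_demo <- function(out_dir, seed = 1, n_traits = 20, set_size = 10) {
  cfg <- demo_cohort_config(seed)
  paths <- write_cohort(cfg, out_dir, n_traits = n_traits,
                        set_size = set_size)
  run_config(msp = paths$msp, bed = paths$bed, gmt = paths$gmt,
             seed = seed, out_dir = file.path(out_dir, "results"))
}
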