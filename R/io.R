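# Readers/writers for the external formats the screen consumes:
# RFMix-v2-style msp local-ancestry tables, BED4 gene models, GMT trait
# gene sets, and per-position selection-score tracks.

#' Read an RFMix-style msp local-ancestry file
#'
#' The dialect follows RFMix v2 `msp.tsv` output: a first header line
#' `#Subpopulation order/codes: LABEL=0<TAB>LABEL=1...`, a second header line
#' `#chm spos epos sgpos egpos n snps SAMPLE.0 SAMPLE.1 ...`, then one row
#' per ancestry-calling window with integer ancestry codes (two columns per
#' sample). Window bounds `spos`/`epos` are treated as 0-based half-open and
#' must tile the chromosome contiguously. As an extension, code `-1` marks
#' windows whose call fell below the caller's confidence threshold
#' (unassigned); files without any `-1` are the normal case. Adjacent
#' windows with equal ancestry are merged into maximal tracts on read.
#'
#' If the genetic-position columns are absent or all zero, a constant
#' 1 cM/Mb map is imputed.
#'
#' @param path Path to the msp file.
#' @param palette Optional [ancestry_palette()]; taken from the header when
#'   `NULL`.
#' @param population Population label; defaults to the file name stem.
#' @return A [haplotype_panel()].
#' @export
read_msp <- function(path, palette = NULL, population = NULL) {
  if (!file.exists(path)) stop("msp file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1], "#Subpopulation order/codes:"))
    stop("malformed msp header: missing '#Subpopulation order/codes:' line")
  codespec <- sub("^#Subpopulation order/codes:\\s*", "", lines[1])
  pairs <- strsplit(trimws(codespec), "\t")[[1]]
  kv <- strsplit(pairs, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) stop("malformed msp header: bad code entry")
  hdr_labels <- vapply(kv, `[`, "", 1)
  hdr_codes <- suppressWarnings(as.integer(vapply(kv, `[`, "", 2)))
  if (anyNA(hdr_codes) || !identical(sort(hdr_codes), seq_along(hdr_codes) - 1L))
    stop("malformed msp header: codes must be contiguous from 0")
  hdr_pal <- ancestry_palette(hdr_labels[order(hdr_codes)])
  if (is.null(palette)) {
    palette <- hdr_pal
  } else if (!identical(palette$labels, hdr_pal$labels)) {
    stop("supplied palette disagrees with msp header (",
         paste(hdr_pal$labels, collapse = ","), ")")
  }

  if (!startsWith(lines[2], "#")) stop("malformed msp header: missing column line")
  cols <- strsplit(sub("^#", "", lines[2]), "\t")[[1]]
  if (length(cols) < 8 || (length(cols) - 6) %% 2 != 0)
    stop("malformed msp header: expected 6 leading columns then 2 per sample")
  hapcols <- cols[-(1:6)]
  samples <- unique(sub("\\.[01]$", "", hapcols))
  expect <- paste0(rep(samples, each = 2), ".", c(0L, 1L))
  if (!identical(hapcols, expect))
    stop("malformed msp header: sample columns must come as SAMPLE.0, SAMPLE.1 pairs")

  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (!length(body)) stop("msp file has no windows")
  tab <- utils::read.table(text = body, sep = "\t", header = FALSE,
                           colClasses = c("character", rep("numeric", 5),
                                          rep("integer", length(hapcols))))
  if (ncol(tab) != length(cols)) stop("msp rows do not match header column count")
  if (length(unique(tab[[1]])) != 1) stop("msp windows span multiple chromosomes")
  spos <- tab[[2]]; epos <- tab[[3]]
  if (any(epos <= spos)) stop("msp structure error: empty or inverted window")
  if (is.unsorted(spos, strictly = TRUE))
    stop("msp structure error: windows out of order or overlapping")
  if (nrow(tab) > 1 && any(spos[-1] != epos[-nrow(tab)]))
    stop("msp structure error: windows overlap or leave gaps")
  span <- c(spos[1], epos[nrow(tab)])

  sg <- tab[[4]]; eg <- tab[[5]]
  map <- if (all(sg == 0) && all(eg == 0)) {
    recomb_map(bp = span, cM = c(0, (span[2] - span[1]) / 1e6))
  } else {
    if (any(eg < sg)) stop("msp structure error: genetic positions not monotone")
    recomb_map(bp = c(spos[1], epos), cM = c(sg[1], eg))
  }

  K <- palette$K
  codes <- as.matrix(tab[, -(1:6), drop = FALSE])
  bad <- codes != UNASSIGNED & (codes < 0 | codes >= K)
  if (any(bad))
    stop("msp code error: ancestry code outside palette: ",
         paste(unique(codes[bad]), collapse = ","))
  haplotypes <- lapply(seq_len(ncol(codes)), function(j) {
    list(ends = epos, anc = codes[, j])
  })

  if (is.null(population)) population <- sub("\\.msp(\\.tsv)?$", "", basename(path))
  haplotype_panel(population, samples, haplotypes, palette,
                  chrom = tab[[1]][1], span = span, map = map)
}

#' Write a haplotype panel as an msp file
#'
#' Emits the dialect read by [read_msp()]: windows are the union of all
#' haplotypes' tract breakpoints, so `read_msp(write_msp(panel))` reproduces
#' the panel exactly (tracts are canonical after merging). Genetic positions
#' come from the panel's recombination map. The `n snps` column is not
#' meaningful for simulated panels and is written as 1.
#'
#' @param panel A [haplotype_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  pal <- panel$palette
  l1 <- paste0("#Subpopulation order/codes: ",
               paste(sprintf("%s=%d", pal$labels, pal$codes), collapse = "\t"))
  l2 <- paste(c("#chm", "spos", "epos", "sgpos", "egpos", "n snps",
                names(panel$haplotypes)), collapse = "\t")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(l1, l2), con)
  if (!length(panel$haplotypes)) return(invisible(path))

  breaks <- sort(unique(c(panel$span[1],
                          unlist(lapply(panel$haplotypes, `[[`, "ends")))))
  spos <- breaks[-length(breaks)]
  epos <- breaks[-1]
  codemat <- vapply(panel$haplotypes, function(h) {
    starts <- .hap_starts(h, panel$span)
    h$anc[findInterval(spos, starts)]
  }, integer(length(spos)))
  codemat <- matrix(codemat, nrow = length(spos))
  rows <- paste(
    panel$chrom,
    format(spos, scientific = FALSE, trim = TRUE),
    format(epos, scientific = FALSE, trim = TRUE),
    sprintf("%.6f", bp_to_cM(panel$map, spos)),
    sprintf("%.6f", bp_to_cM(panel$map, epos)),
    1L,
    apply(codemat, 1, paste, collapse = "\t"),
    sep = "\t")
  writeLines(rows, con)
  invisible(path)
}

#' Read gene models from a BED4 file
#'
#' @param path Path to a tab-separated BED4 file (`chrom start end name`,
#'   0-based half-open, no header).
#' @return data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name"),
                          colClasses = c("character", "numeric", "numeric",
                                         "character"))
  if (any(df$start >= df$end)) stop("BED error: start must be < end")
  if (anyDuplicated(df$name)) stop("BED error: duplicate gene names")
  df
}

#' Read trait gene sets from a GMT file
#'
#' Each tab-separated line is `trait <TAB> description <TAB> gene1 ...`.
#'
#' @param path Path to the GMT file.
#' @return Named list of `trait_set` objects (`trait`, `description`,
#'   `genes`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT error: empty gene set for trait '", f[1], "'")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT error: empty gene set for trait '", f[1], "'")
    if (anyDuplicated(genes)) {
      warning("GMT: duplicate genes in trait '", f[1], "' collapsed")
      genes <- unique(genes)
    }
    trait_set(f[1], f[2], genes)
  })
  names(out) <- vapply(out, `[[`, "", "trait")
  if (anyDuplicated(names(out))) stop("GMT error: duplicate trait names")
  out
}

#' Construct a trait gene set
#'
#' @param trait Trait name.
#' @param description Free-text description.
#' @param genes Character vector of unique gene names (non-empty).
#' @return Object of class `trait_set`.
#' @export
trait_set <- function(trait, description = "", genes = character()) {
  genes <- as.character(genes)
  if (!length(genes)) stop("a trait set must contain at least one gene")
  if (anyDuplicated(genes)) stop("trait set genes must be unique")
  structure(list(trait = trait, description = description, genes = genes),
            class = "trait_set")
}

#' Write trait gene sets to a GMT file
#'
#' @param traits List of `trait_set` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(traits, path) {
  lines <- vapply(traits, function(ts) {
    paste(c(ts$trait, ts$description, ts$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-position selection-score track
#'
#' Two dialects are supported: `selscan_norm`, the normalized output of
#' selscan (columns `id pos freq ihh1 ihh0 ihs ihs_std crit`, no header; the
#' standardized-score column is taken as the score), and `generic_tsv`, a
#' two-column `pos score` table with optional header. Positions must be
#' strictly increasing.
#'
#' @param path Path to the track file.
#' @param dialect `"generic_tsv"` or `"selscan_norm"`.
#' @param label Track label; defaults to the file name stem.
#' @return Object of class `score_track` with `positions`, `scores`, `label`.
#' @export
read_score_track <- function(path, dialect = c("generic_tsv", "selscan_norm"),
                             label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("score track not found: ", path)
  if (dialect == "selscan_norm") {
    df <- utils::read.table(path, sep = "\t", header = FALSE)
    if (ncol(df) < 7) stop("selscan_norm track needs >= 7 columns")
    pos <- as.numeric(df[[2]])
    sc <- as.numeric(df[[7]])
  } else {
    first <- strsplit(readLines(path, n = 1), "\t")[[1]]
    has_header <- suppressWarnings(is.na(as.numeric(first[1])))
    df <- utils::read.table(path, sep = "\t", header = has_header)
    if (ncol(df) < 2) stop("generic_tsv track needs 2 columns (pos, score)")
    pos <- as.numeric(df[[1]])
    sc <- as.numeric(df[[2]])
  }
  if (anyNA(pos) || anyNA(sc)) stop("score track: non-numeric values")
  if (is.unsorted(pos, strictly = TRUE))
    stop("score track: positions must be strictly increasing")
  structure(list(positions = pos, scores = sc,
                 label = label %||% sub("\\.[^.]*$", "", basename(path))),
            class = "score_track")
}
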