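# Haplotype panels: the in-memory image of RFMix-style local-ancestry calls.
#
# Each haplotype is stored compactly as a pair of vectors: the tract end
# positions (`ends`, 0-based half-open, last end == chromosome span end) and
# the integer ancestry codes (`anc`, palette codes or -1 for UNASSIGNED).
# Tract starts are implicit (span start, then the previous end). Adjacent
# tracts with equal ancestry are always merged, so tract identity is
# canonical. This layout keeps the Wright-Fisher simulator and the gene scan
# fast; `panel_tracts()` converts to a tidy per-tract table.

.hap_starts <- function(hap, span) {
  n <- length(hap$ends)
  if (n == 0) return(numeric(0))
  c(span[1], hap$ends[-n])
}

.merge_hap <- function(hap) {
  r <- rle(hap$anc)
  if (length(r$lengths) == length(hap$anc)) return(hap)
  list(ends = hap$ends[cumsum(r$lengths)], anc = r$values)
}

.validate_hap <- function(hap, span, K, what = "haplotype") {
  ends <- hap$ends
  anc <- hap$anc
  if (length(ends) != length(anc) || length(ends) == 0)
    stop(what, ": tract vectors empty or of unequal length")
  if (is.unsorted(ends, strictly = TRUE))
    stop(what, ": tract ends not strictly increasing (overlap or empty tract)")
  if (ends[1] <= span[1] || abs(ends[length(ends)] - span[2]) > 0)
    stop(what, ": tracts do not exactly tile the chromosome span")
  bad <- anc < -1L | anc >= K
  if (any(bad)) stop(what, ": ancestry code outside palette: ",
                     paste(unique(anc[bad]), collapse = ","))
  invisible(TRUE)
}

#' Construct a haplotype panel
#'
#' A panel holds the phased local-ancestry calls of one population on one
#' chromosome: two haplotypes per sample, each a contiguous partition of the
#' chromosome into ancestry-labelled tracts. Every haplotype must tile the
#' chromosome span exactly (no gaps, no overlaps); adjacent tracts of equal
#' ancestry are merged on construction.
#'
#' @param population Population label.
#' @param samples Character vector of sample ids.
#' @param haplotypes List of length `2 * length(samples)` (sample-major,
#'   haplotype 0 then 1), each element `list(ends = , anc = )` with tract end
#'   positions (bp, 0-based half-open) and integer ancestry codes (`-1` for
#'   unassigned).
#' @param palette An [ancestry_palette()].
#' @param chrom Chromosome name.
#' @param span Numeric length-2 `(start_bp, end_bp)` of the chromosome.
#' @param map Optional [recomb_map()]; defaults to a constant 1 cM/Mb map.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(population, samples, haplotypes, palette,
                            chrom, span, map = NULL) {
  stopifnot(inherits(palette, "ancestry_palette"),
            length(span) == 2, span[1] < span[2])
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  if (length(haplotypes) != 2 * length(samples))
    stop("need exactly 2 haplotypes per sample")
  haplotypes <- lapply(haplotypes, function(h) {
    h$anc <- as.integer(h$anc)
    .merge_hap(h)
  })
  if (is.null(map)) map <- recomb_map(span[2] - span[1], 1)
  names(haplotypes) <- if (length(samples))
    paste0(rep(samples, each = 2), ".", c(0L, 1L)) else character(0)
  panel <- structure(
    list(population = population, samples = samples,
         haplotypes = haplotypes, palette = palette,
         chrom = chrom, span = as.numeric(span), map = map),
    class = "haplotype_panel"
  )
  validate_haplotype_panel(panel)
  panel
}

#' Validate a haplotype panel's structural invariants
#'
#' Checks that every haplotype exactly tiles the chromosome span with
#' strictly increasing tract ends and ancestry codes inside the palette
#' (or `-1`). Coverage conservation (sum of tract lengths equals the span
#' length) follows from the tiling check.
#'
#' @param panel A `haplotype_panel`.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_haplotype_panel <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  K <- panel$palette$K
  for (i in seq_along(panel$haplotypes)) {
    .validate_hap(panel$haplotypes[[i]], panel$span, K,
                  what = names(panel$haplotypes)[i] %||% paste0("hap ", i))
  }
  invisible(TRUE)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "haplotype_panel: %s, %d samples (%d haplotypes), %s:[%s,%s), K=%d\n",
    x$population, length(x$samples), length(x$haplotypes), x$chrom,
    format(x$span[1], scientific = FALSE),
    format(x$span[2], scientific = FALSE), x$palette$K))
  invisible(x)
}

#' Tidy per-tract table of a panel
#'
#' @param panel A `haplotype_panel`.
#' @return A data.frame with one row per tract: `sample`, `haplotype` (0/1),
#'   `chrom`, `start_bp`, `end_bp`, `start_cM`, `end_cM`, `code`, `ancestry`
#'   (label, or `"UNASSIGNED"`).
#' @export
panel_tracts <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  out <- lapply(seq_along(panel$haplotypes), function(i) {
    h <- panel$haplotypes[[i]]
    starts <- .hap_starts(h, panel$span)
    data.frame(
      sample = panel$samples[(i + 1) %/% 2],
      haplotype = (i + 1) %% 2,
      chrom = panel$chrom,
      start_bp = starts, end_bp = h$ends,
      start_cM = bp_to_cM(panel$map, starts),
      end_cM = bp_to_cM(panel$map, h$ends),
      code = h$anc,
      ancestry = ifelse(h$anc < 0, "UNASSIGNED",
                        panel$palette$labels[h$anc + 1L]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Genome-wide ancestry fractions of a panel
#'
#' Length-weighted fraction of each palette ancestry among assigned tract
#' length, plus the unassigned length fraction as an attribute.
#'
#' @param panel A `haplotype_panel`.
#' @return Named numeric vector over palette labels summing to 1 (attribute
#'   `unassigned` gives the unassigned length share of total length).
#' @export
panel_ancestry_fractions <- function(panel) {
  K <- panel$palette$K
  len <- numeric(K)
  un <- 0
  for (h in panel$haplotypes) {
    w <- diff(c(panel$span[1], h$ends))
    for (k in seq_len(K)) len[k] <- len[k] + sum(w[h$anc == (k - 1L)])
    un <- un + sum(w[h$anc == UNASSIGNED])
  }
  tot <- sum(len)
  out <- if (tot > 0) len / tot else rep(NA_real_, K)
  names(out) <- panel$palette$labels
  attr(out, "unassigned") <- un / (tot + un)
  out
}
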