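#' Ancestry palette
#'
#' An ordered set of ancestry labels with integer codes `0..K-1`, matching the
#' subpopulation code line of RFMix-style local-ancestry output. The screen in
#' this package was designed for three continental ancestries (African,
#' European, Native American), but any `K >= 2` is accepted. The sentinel code
#' `-1` (`UNASSIGNED`) marks haplotype segments whose ancestry call fell below
#' the caller's confidence threshold and is never part of the palette itself.
#'
#' @param labels Character vector of unique ancestry names, in code order.
#' @return An object of class `ancestry_palette` with fields `labels`,
#'   `codes` (integers `0..K-1`) and `K`.
#' @examples
#' ancestry_palette(c("AFR", "EUR", "NAT"))
#' @export
ancestry_palette <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2) stop("an ancestry palette needs K >= 2 labels")
  if (anyDuplicated(labels)) stop("ancestry labels must be unique")
  structure(
    list(labels = labels, codes = seq_along(labels) - 1L,
         K = length(labels)),
    class = "ancestry_palette"
  )
}

#' @export
print.ancestry_palette <- function(x, ...) {
  cat("ancestry_palette:",
      paste(sprintf("%s=%d", x$labels, x$codes), collapse = " "), "\n")
  invisible(x)
}

UNASSIGNED <- -1L

#' Recombination map
#'
#' Piecewise-linear map between physical (bp) and genetic (cM) coordinates.
#' A constant-rate map is the common case; a piecewise map can be given as
#' matching vectors of knot positions.
#'
#' @param chrom_length_bp Chromosome length in bp (constant-rate form).
#' @param cM_per_Mb Constant recombination rate (default 1 cM/Mb).
#' @param bp,cM Optional knot vectors (both increasing, same length,
#'   starting at the chromosome start) defining a piecewise-linear map;
#'   overrides the constant form.
#' @return Object of class `recomb_map` with `$bp_to_cM()` / `$cM_to_bp()`.
#' @export
recomb_map <- function(chrom_length_bp = NULL, cM_per_Mb = 1,
                       bp = NULL, cM = NULL) {
  if (is.null(bp)) {
    stopifnot(is.numeric(chrom_length_bp), chrom_length_bp > 0, cM_per_Mb > 0)
    bp <- c(0, chrom_length_bp)
    cM <- c(0, chrom_length_bp / 1e6 * cM_per_Mb)
  }
  stopifnot(length(bp) == length(cM), length(bp) >= 2,
            !is.unsorted(bp, strictly = TRUE), !is.unsorted(cM))
  m <- structure(list(bp = as.numeric(bp), cM = as.numeric(cM)),
                 class = "recomb_map")
  m
}

bp_to_cM <- function(map, x) {
  stats::approx(map$bp, map$cM, xout = x, rule = 2)$y
}

cM_to_bp <- function(map, x) {
  # a flat segment (zero recombination) would make the inverse non-unique;
  # nudge duplicated cM knots by a negligible epsilon
  cm <- map$cM
  dup <- duplicated(cm)
  if (any(dup)) cm[dup] <- cm[dup] + cumsum(dup)[dup] * 1e-9
  stats::approx(cm, map$bp, xout = x, rule = 2)$y
}

map_length_cM <- function(map) map$cM[length(map$cM)] - map$cM[1]
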