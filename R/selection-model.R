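# Tri-allelic recursive selection model on ancestry-haplotype frequencies.
#
# Three allelic states correspond to the three ancestry components; the
# favored ancestry haplotype has genic (multiplicative) fitness 1 + s and
# the other two are selectively equivalent. One generation of selection:
#   p' = p (1 + s) / wbar,  q_j' = q_j / wbar,  wbar = 1 + s p,
# which preserves the frequency simplex exactly and gives the closed form
# p_t / (1 - p_t) = (1 + s)^t * p_0 / (1 - p_0). Model output is expressed
# on the same z-score scale as the enrichment scan by standardizing the
# favored-ancestry frequency with the scan's genome-wide moments, so an
# observed enrichment z maps back to the selection coefficient s that
# produces it after t generations.

#' Construct a selection-model state
#'
#' @param freqs Named numeric vector of ancestry-haplotype frequencies
#'   (non-negative, summing to 1 within 1e-12).
#' @param favored Favored ancestry: index or name into `freqs`.
#' @param s Selection coefficient (`s >= -1`).
#' @param t Generation counter (default 0).
#' @return Object of class `selection_state`.
#' @export
selection_state <- function(freqs, favored, s, t = 0L) {
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-12)
    stop("freqs must be non-negative and sum to 1")
  if (is.character(favored)) favored <- match(favored, names(freqs))
  if (is.na(favored) || favored < 1 || favored > length(freqs))
    stop("favored must index an ancestry in freqs")
  if (s < -1) stop("s must be >= -1")
  structure(list(freqs = freqs, favored = as.integer(favored),
                 s = s, t = as.integer(t)),
            class = "selection_state")
}

#' Advance the selection recursion by one generation
#'
#' @param state A [selection_state()].
#' @return The state after one generation of genic selection.
#' @export
selection_step <- function(state) {
  stopifnot(inherits(state, "selection_state"))
  p <- state$freqs[state$favored]
  wbar <- 1 + state$s * p
  if (wbar <= 0) stop("mean fitness <= 0 (s too negative)")
  freqs <- state$freqs / wbar
  freqs[state$favored] <- p * (1 + state$s) / wbar
  state$freqs <- freqs
  state$t <- state$t + 1L
  state
}

#' Frequency and enrichment trajectory under selection
#'
#' Iterates the recursion for `t` generations and expresses the
#' favored-ancestry frequency on the enrichment z scale at each generation.
#'
#' @param p0 Named initial frequency vector.
#' @param favored Favored ancestry (index or name).
#' @param s Selection coefficient.
#' @param t Number of generations (`>= 0`).
#' @param mu_anc,sigma_anc Genome-wide mean and SD of the favored
#'   ancestry's gene-level fraction (the scan's moments).
#' @return data.frame with `generation`, one column per ancestry, and `z`.
#' @export
selection_trajectory <- function(p0, favored, s, t, mu_anc, sigma_anc) {
  stopifnot(t >= 0, sigma_anc > 0)
  state <- selection_state(p0, favored, s)
  rows <- vector("list", t + 1)
  for (gen in 0:t) {
    rows[[gen + 1]] <- c(generation = gen, state$freqs,
                         z = (state$freqs[[state$favored]] - mu_anc) /
                           sigma_anc)
    if (gen < t) state <- selection_step(state)
  }
  as.data.frame(do.call(rbind, rows))
}

#' Terminal enrichment z implied by a selection coefficient
#'
#' Runs the favored-ancestry frequency forward `t` generations from `p0`
#' (by default the genome-wide background fraction `mu_anc`) and returns
#' its z-score against the scan's genome-wide moments. Strictly increasing
#' in `s` for `p0` in (0, 1).
#'
#' @param s Selection coefficient.
#' @param t Generations.
#' @param mu_anc,sigma_anc Genome-wide moments of the favored ancestry.
#' @param p0 Initial favored-ancestry frequency (default `mu_anc`).
#' @return The terminal z value.
#' @export
z_from_s <- function(s, t, mu_anc, sigma_anc, p0 = mu_anc) {
  if (sigma_anc <= 0) stop("sigma_anc must be positive")
  stopifnot(t >= 0, p0 >= 0, p0 <= 1, s >= -1)
  p <- p0
  for (gen in seq_len(t)) {
    wbar <- 1 + s * p
    if (wbar <= 0) stop("mean fitness <= 0 (s too negative)")
    p <- p * (1 + s) / wbar
  }
  (p - mu_anc) / sigma_anc
}

#' Infer the selection coefficient matching an observed enrichment
#'
#' Bisection on the monotone map `s -> z_from_s(s, ...)`; recovers `s`
#' to within `tol`.
#'
#' @param z_obs Observed enrichment z for the favored ancestry.
#' @param t Generations of selection assumed.
#' @param mu_anc,sigma_anc Genome-wide moments of the favored ancestry.
#' @param p0 Initial favored-ancestry frequency (default `mu_anc`).
#' @param tol Tolerance on `s` (default 1e-8).
#' @param s_bounds Search interval (default `[0, 1]`).
#' @return The inferred selection coefficient `s_hat`.
#' @export
infer_s <- function(z_obs, t, mu_anc, sigma_anc, p0 = mu_anc,
                    tol = 1e-8, s_bounds = c(0, 1)) {
  lo <- s_bounds[1]
  hi <- s_bounds[2]
  z_lo <- z_from_s(lo, t, mu_anc, sigma_anc, p0)
  z_hi <- z_from_s(hi, t, mu_anc, sigma_anc, p0)
  if (z_obs < z_lo || z_obs > z_hi)
    stop(sprintf(
      "z_obs = %.4g outside the achievable range [%.4g, %.4g] for s in [%g, %g]",
      z_obs, z_lo, z_hi, lo, hi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (z_from_s(mid, t, mu_anc, sigma_anc, p0) < z_obs) lo <- mid
    else hi <- mid
  }
  (lo + hi) / 2
}

#' Fit selection coefficients across populations
#'
#' Inverts the observed favored-ancestry enrichment of each population to a
#' selection coefficient and averages across populations. Because the model
#' attributes the whole observed enrichment to post-admixture selection,
#' the estimates are upper bounds.
#'
#' @param z_obs Named numeric vector of observed z per population.
#' @param mu_anc,sigma_anc Numeric vectors (recycled) of each population's
#'   genome-wide moments for the favored ancestry.
#' @param t Generations of selection assumed (default 20).
#' @param ... Passed to [infer_s()].
#' @return Object of class `selection_fit`: `table` (per-population
#'   `s_hat`), `mean_s`, `t`, `note`.
#' @export
fit_populations <- function(z_obs, mu_anc, sigma_anc, t = 20, ...) {
  stopifnot(length(z_obs) >= 1)
  mu_anc <- rep_len(mu_anc, length(z_obs))
  sigma_anc <- rep_len(sigma_anc, length(z_obs))
  s_hat <- vapply(seq_along(z_obs), function(i) {
    infer_s(z_obs[i], t, mu_anc[i], sigma_anc[i], ...)
  }, 0)
  tab <- data.frame(
    population = names(z_obs) %||% paste0("pop", seq_along(z_obs)),
    z_obs = as.numeric(z_obs), mu_anc = mu_anc, sigma_anc = sigma_anc,
    t = t, s_hat = s_hat, stringsAsFactors = FALSE)
  structure(list(table = tab, mean_s = mean(s_hat), t = t,
                 note = paste("s_hat attributes all observed enrichment to",
                              "post-admixture selection and is therefore",
                              "an upper-bound estimate")),
            class = "selection_fit")
}

#' @export
print.selection_fit <- function(x, ...) {
  print(x$table)
  cat(sprintf("mean s across populations: %.4f (t = %d)\n", x$mean_s, x$t))
  cat("note:", x$note, "\n")
  invisible(x)
}
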