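# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions do not perturb the session stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific seed from a global seed
#'
#' Hashes a stage label into the seed so that pipeline stages draw from
#' distinct, reproducible streams. Result is a positive 32-bit integer.
#'
#' @param seed Integer global seed.
#' @param stage Character label of the stage.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  codes <- utf8ToInt(paste(stage, collapse = "/"))
  # doubles stay exact below 2^53; keep intermediate products small
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 1000000007
  as.integer((abs(seed) %% 1000003) * 1009 + h %% 2147481563) %% .Machine$integer.max
}

# Largest-remainder apportionment of n into round(n * p) integer counts.
largest_remainder <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-9, n >= 0)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Write a results table as TSV with a single header row.
write_result_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
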