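#' Round half away from zero
#'
#' Fixed-precision rounding that breaks ties away from zero (the convention
#' used in the campaign's printed tables), unlike [base::round()]'s
#' round-half-even.
#'
#' @param x numeric vector
#' @param digits integer, decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so generators are reproducible without clobbering
#' the caller's stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
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
  expr
}

# FNV-1a 32-bit hash of a string; used only to stamp config hashes into
# report headers (no cryptographic intent).
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keeps h clear of bitwXor's
    # 31-bit limit
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b %% 256)
    # 32-bit modular multiply in 16-bit halves to stay inside double precision
    h0 <- h %% 65536
    h1 <- h %/% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Hash a configuration object
#'
#' Stable short hash of any R object (via its canonical JSON form), stamped
#' into output-file headers so a run can be tied to its configuration.
#'
#' @param config any jsonlite-serializable object
#' @return 8-hex-digit character hash
#' @export
config_hash <- function(config) {
  fnv1a32(as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
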