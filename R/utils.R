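#' Derive a child RNG seed from a top-level seed and index path
#'
#' The synthetic-data generators expand one user-facing seed into independent
#' per-cell / per-pixel streams through a counter-based mixing scheme, so that
#' outputs are byte-stable across runs and insensitive to the order in which
#' cells are generated.
#'
#' @param seed integer top-level seed.
#' @param ... integer indices identifying the stream (construct, batch, cell,
#'   component, ...).
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @keywords internal
child_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime; all arithmetic stays < 2^53
  s <- as.numeric(seed) %% m
  for (idx in c(...)) {
    s <- (s * 48271 + (as.numeric(idx) + 1) * 16807) %% m
    s <- (s * 69621) %% m
  }
  as.integer(s %% (m - 2)) + 1L
}

#' Evaluate with a temporary RNG state
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# FNV-1a hash of a character scalar, reported as 8 hex digits; used only to
# fingerprint report provenance (config + seed), not for security.
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), as.integer(b)) + 2^30
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
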