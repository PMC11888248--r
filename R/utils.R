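# Internal helpers shared across the package.

#' Derive a named sub-stream seed from a global seed
#'
#' Deterministically maps a (seed, stream-name) pair to an integer seed below
#' 2^31 so that independent stages of a stochastic pipeline can be regenerated
#' in isolation from one master seed.
#'
#' @param seed Integer master seed.
#' @param stream Character stream name (e.g. `"programs"`, `"sampling"`).
#' @return A single integer seed.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 1000003
  as.integer((abs(seed) %% 1000003) * 1009 + h * 31 + 7) %% 2147483647L
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# which.max with deterministic ties: smallest name (then smallest index).
# Returns the index; attribute "tie" records whether a tie occurred.
argmax_tiebreak <- function(x, names = base::names(x)) {
  m <- max(x)
  cand <- which(x >= m - .Machine$double.eps * 64 & x == m)
  tie <- length(cand) > 1L
  idx <- if (tie && !is.null(names)) cand[order(names[cand])][1L] else cand[1L]
  structure(idx, tie = tie)
}

# Mid-ranks (average method), NA-free input assumed.
midrank <- function(x) rank(x, ties.method = "average")

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_atlasrep <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)
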