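# Internal helpers shared across modules.

#' Derive a reproducible substream seed from a master seed
#'
#' Every stochastic component of the pipeline (trajectory, photometry,
#' pixel-change, counts, sweeps) draws its seed from one master seed through
#' this splitting rule, so stages can be re-simulated independently while a
#' single `--seed` reproduces a whole run.  The rule is a fixed affine map
#' modulo the Mersenne prime 2^31 - 1: distinct `stream` indices give distinct
#' seeds for any master seed.
#'
#' @param seed master seed (non-negative integer below 2^31).
#' @param stream integer substream index (0, 1, 2, ...).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(42, 0)
#' substream_seed(42, 1)
substream_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0,
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  m <- 2147483647 # 2^31 - 1; all arithmetic stays < 2^53, exact in doubles
  s <- (as.double(seed) %% m) * 48271 %% m
  s <- (s + (as.double(stream) + 1) * 16807) %% m
  as.integer(s %% (m - 2) + 1)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
# `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Trapezoid integral of y over x.
trapezoid <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# Format numbers for byte-stable serialized output: 9 significant digits.
stable_num <- function(x) signif(x, 9)

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
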