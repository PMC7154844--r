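# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a named sub-stream seed from a global seed so that adding a
# generator never perturbs the draws of another. Stays below 2^31.
stream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 1000003L
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Plain "schoolbook" rounding (0.5 always rounds up), as used when
#' reconstructing printed percentage values; `base::round` rounds half to
#' even and would disagree on exact halves.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5 + 1e-9) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
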