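#' Derive a reproducible 31-bit seed from a master seed and a string key
#'
#' All stochastic stages draw their randomness from named substreams derived
#' from one master seed, so results are independent of the order in which
#' units (windows, sites, branches) are processed.
#'
#' @param seed Integer master seed.
#' @param ... Character or numeric key components naming the substream,
#'   e.g. `("window", 17)` or `("het", chrom, pos, sample)`.
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
substream_seed <- function(seed, ...) {
  if (is.null(seed) || length(seed) != 1L || is.na(seed))
    stop("a seed is required for stochastic stages")
  m <- 2147483647  # 2^31 - 1, prime; all arithmetic stays exact in doubles
  key <- paste(vapply(list(...), function(x)
    paste(format(x, scientific = FALSE, trim = TRUE), collapse = "\r"),
    character(1)), collapse = "\x1f")
  h <- as.numeric(seed) %% m
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% m
  # final scramble so nearby keys decorrelate
  h <- (h * 48271) %% m
  h <- (h * 48271) %% m
  as.integer(h)
}

#' Evaluate an expression under a substream seed, restoring global RNG state
#'
#' @param seed Integer master seed.
#' @param key List of key components (passed to [substream_seed()]).
#' @param expr Expression to evaluate with the substream seed set.
#' @keywords internal
with_substream <- function(seed, key, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(do.call(substream_seed, c(list(seed), key)))
  expr
}

#' Deterministic uniform draw tied to a master seed and a unit key
#'
#' The same `(seed, key)` gives the same draw no matter when or in what
#' order the unit is visited.
#' @inheritParams with_substream
#' @return A single uniform draw in (0, 1).
#' @keywords internal
unit_runif <- function(seed, key) {
  with_substream(seed, key, stats::runif(1))
}
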