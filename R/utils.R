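# Internal helpers shared across modules.

# Parental-origin codes used throughout: 0 = P1 (reference parent),
# 1 = P2 (alternative parent), NA = unknown.
P1_CODE <- 0L
P2_CODE <- 1L

#' Derive a reproducible substream seed from a master seed
#'
#' All stochastic stages draw their RNG state from a single master seed via
#' named substreams, so each stage is independently reproducible. The
#' derived seed is kept strictly below 2^31.
#'
#' @param seed Master seed (single integer).
#' @param stream Character name of the substream (e.g. `"cross"`, `"reads"`).
#' @return A single integer seed.
#' @export
#' @examples
#' substream_seed(1, "cross")
substream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1, is.finite(seed), is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 1998244353
  as.integer((abs(seed) * 48271 + h) %% 2147483647L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

site_id <- function(chrom, pos) paste0(chrom, ":", pos)
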