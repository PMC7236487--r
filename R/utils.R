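#' @keywords internal
"_PACKAGE"

## Seed streams: one user-facing seed deterministically spawns per-stage
## substreams so simulate / fit / predict / evaluate never share a stream.
## Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 2654435761 + h * 97 + 49297) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

cfj_log <- function(level, ...) {
  lvl <- getOption("cfjoint.verbose", 1L)
  if (lvl >= level) message(sprintf("[cfjoint] %s", paste0(...)))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## group sums by integer index (1..n); dense result of length n
group_sum <- function(x, index, n) {
  out <- numeric(n)
  s <- rowsum(x, group = index, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}
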