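#' Derive a reproducible sub-stream seed
#'
#' One root seed governs a whole analysis; each stochastic operation derives
#' its own seed by hashing the root seed with a stage tag, so any stage can be
#' re-run in isolation with an identical random stream.
#'
#' @param seed Integer root seed.
#' @param tag Character tag naming the operation (and, if needed, a counter).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(42, "splits")
#' derive_seed(42, "splits") == derive_seed(42L, "splits")
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  h <- as.double(abs(as.integer(seed)) %% 2147483647)
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# set.seed() scoped to a derived sub-stream; restores the caller's RNG state
with_substream <- function(seed, tag, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, tag))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
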