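# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so substreams do not perturb each other.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic 31-bit substream seed from a base seed and a counter
substream_seed <- function(seed, counter) {
  as.integer((as.double(seed %% 65536L) * 40503 + counter * 69069) %% 2147483647)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
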