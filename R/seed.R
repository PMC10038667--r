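# Seed plumbing: every stochastic operation takes an explicit integer seed,
# evaluated in a local RNG scope so the caller's random state is untouched.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage seed from a global seed and an operation tag
#'
#' Deterministic mixing of an integer seed with a short string tag, so that
#' pipeline stages draw from independent streams while the whole run remains
#' reproducible from one global seed. The result is always in `[1, 2^31 - 2]`.
#'
#' @param seed Integer global seed.
#' @param tag Character tag naming the stage (e.g. `"r20"`).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, tag) {
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}
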