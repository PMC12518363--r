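# Deterministic substream seeding: every stochastic component draws from a
# seed derived from (master seed, component name), so adding grains or stages
# never perturbs the random numbers used by earlier ones.

#' Derive a substream seed from a master seed and a component name
#'
#' Polynomial rolling hash of `name` combined with `seed`, reduced modulo
#' 2^31 - 1 so the result is always a valid 32-bit R seed.
#'
#' @param seed integer master seed.
#' @param name character scalar naming the component/substream.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(42, "plate1.grain3")
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name),
            length(name) == 1L)
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% m
  as.integer((h + (abs(as.numeric(seed)) %% m) * 7919) %% m)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}
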