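# Internal helpers shared across modules.

# Deterministic 31-bit string hash (polynomial rolling hash). Used to derive
# per-stage seeds from a single global seed so stages can be re-run in
# isolation; must stay below 2^31 because R seeds are 32-bit integers.
str_hash31 <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + str_hash31(stage)) %% 2147483647)
}

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count_like <- function(x) {
  v <- if (methods::is(x, "sparseMatrix")) x@x else as.numeric(x)
  all(v >= 0) && all(v == round(v))
}
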