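# Internal helpers.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed for a (seed, labels...) tuple, so that pairwise
# estimates are reproducible and independent of evaluation order.
derive_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  labels <- paste(c(...), collapse = "\r")
  h <- 0
  for (code in utf8ToInt(labels)) h <- (h * 31 + code) %% 1000003L
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
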