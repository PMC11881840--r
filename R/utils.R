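# Internal helpers shared across modules.

# Run fun() under a fixed seed without disturbing the caller's RNG state.
.withSeed <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  fun()
}

# Derive a named sub-stream seed from a master seed; stays below 2^31.
.streamSeed <- function(seed, stream) {
  b <- utf8ToInt(stream)
  h <- sum(b * seq_along(b))
  as.integer((as.numeric(seed) %% 1e6) * 2111 + h * 13 + 1)
}

# Deterministic sign convention: largest-|value| entry of each column > 0.
.fixSigns <- function(U, V = NULL) {
  s <- vapply(seq_len(ncol(U)), function(k) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) -1 else 1
  }, numeric(1))
  U <- sweep(U, 2, s, `*`)
  if (is.null(V)) return(U)
  list(U = U, V = sweep(V, 2, s, `*`))
}

.assertScalarCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x != round(x))
    stop(name, " must be a positive integer", call. = FALSE)
  as.integer(x)
}
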