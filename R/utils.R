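#' @importFrom stats AIC BIC
NULL

# Derive a reproducible sub-stream seed from a master seed and an operation
# tag; keeps every derived seed strictly below 2^31.
subSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# Multivariate normal draws via Cholesky; sigma must be positive definite.
rmvn <- function(n, sigma) {
  L <- chol(sigma)
  matrix(rnorm(n * ncol(sigma)), n) %*% L
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)

logdetChol <- function(U) 2 * sum(log(diag(U)))

# max over columns of a matrix, without apply() overhead
colMax <- function(m) {
  out <- m[1L, ]
  if (nrow(m) > 1L) for (i in 2L:nrow(m)) {
    v <- m[i, ]
    gt <- v > out
    out[gt] <- v[gt]
  }
  out
}
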