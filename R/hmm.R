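# Two-state hidden Markov model for selfed-RIL genomes, vectorized across
# individuals. States: 1 = AA (Brandes, +1), 2 = BB (Wray, -1). The
# transition probability across an interval with gametic recombination
# fraction r is the selfed-RIL recombinant probability R = 2r/(1+2r); the
# chain models the final inbred genome, not per-generation meioses.
# Emissions: an observed call matches the state with probability
# 1 - errorRate; missing calls emit 1.

hmmEmission <- function(obs, errorRate) {
  E1 <- ifelse(is.na(obs), 1, ifelse(obs == 1L, 1 - errorRate, errorRate))
  E2 <- ifelse(is.na(obs), 1, ifelse(obs == -1L, 1 - errorRate, errorRate))
  cbind(E1, E2)
}

# obsMat: positions x individuals (+1/-1/NA; 0 treated as NA);
# R: per-interval recombinant probabilities (length M-1).
# Returns scaled forward/backward quantities, posteriors, per-individual
# log-likelihood and (optionally) expected per-interval recombination
# probabilities for EM.
hmmForwardBackward <- function(obsMat, R, errorRate, wantXi = FALSE) {
  obsMat[obsMat == 0L] <- NA_integer_
  M <- nrow(obsMat); n <- ncol(obsMat)
  A <- array(0, c(n, M, 2))
  B <- array(0, c(n, M, 2))
  cs <- matrix(0, n, M)
  Em <- lapply(seq_len(M), function(m) hmmEmission(obsMat[m, ], errorRate))
  a <- 0.5 * Em[[1]]
  cs[, 1] <- rowSums(a)
  A[, 1, ] <- a / cs[, 1]
  if (M > 1) for (m in 2:M) {
    r <- R[m - 1]
    prev <- matrix(A[, m - 1, ], ncol = 2)
    pred <- cbind(prev[, 1] * (1 - r) + prev[, 2] * r,
                  prev[, 1] * r + prev[, 2] * (1 - r))
    a <- pred * Em[[m]]
    cs[, m] <- rowSums(a)
    A[, m, ] <- a / cs[, m]
  }
  B[, M, ] <- 1
  if (M > 1) for (m in (M - 1):1) {
    r <- R[m]
    nb <- matrix(B[, m + 1, ], ncol = 2) * Em[[m + 1]]
    B[, m, ] <- cbind(nb[, 1] * (1 - r) + nb[, 2] * r,
                      nb[, 1] * r + nb[, 2] * (1 - r)) / cs[, m + 1]
  }
  post <- A * B
  norm <- post[, , 1] + post[, , 2]
  if (M == 1) norm <- matrix(norm, n, 1)
  post[, , 1] <- post[, , 1] / norm
  post[, , 2] <- post[, , 2] / norm
  ll <- rowSums(log(cs))
  xi <- NULL
  if (wantXi && M > 1) {
    xi <- matrix(0, n, M - 1)   # P(state change across interval m)
    for (m in seq_len(M - 1)) {
      r <- R[m]
      nb <- matrix(B[, m + 1, ], ncol = 2) * Em[[m + 1]]
      x11 <- A[, m, 1] * (1 - r) * nb[, 1]
      x12 <- A[, m, 1] * r * nb[, 2]
      x21 <- A[, m, 2] * r * nb[, 1]
      x22 <- A[, m, 2] * (1 - r) * nb[, 2]
      tot <- x11 + x12 + x21 + x22
      xi[, m] <- (x12 + x21) / tot
    }
  }
  list(post = post, loglik = sum(ll), xi = xi)
}
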