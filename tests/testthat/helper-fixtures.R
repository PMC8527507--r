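# Shared fixtures, built in code at test time.

# candidate grid on nchr chromosomes with the given step (cM)
mkGridPositions <- function(nchr, len, step = 1) {
  do.call(rbind, lapply(seq_len(nchr), function(c)
    data.frame(group = paste0("chr", c), cM = seq(0, len, by = step),
               chrom = paste0("chr", c),
               bp = as.integer(seq(0, len, by = step) * 250000 + 1),
               stringsAsFactors = FALSE)))
}

# fully inbred RIL genotype scores at the grid positions, drawn from the
# Haldane-Waddington interval process (independent of the package's
# simulateRILs implementation)
simGridScores <- function(n, pos, seed, mapFunction = "kosambi") {
  set.seed(seed)
  X <- matrix(0, n, nrow(pos))
  for (g in unique(pos$group)) {
    i <- which(pos$group == g)
    d <- diff(pos$cM[i])
    r <- switch(mapFunction,
                kosambi = tanh(d / 50) / 2,
                haldane = (1 - exp(-d / 50)) / 2)
    R <- 2 * r / (1 + 2 * r)
    s <- matrix(0, n, length(i))
    s[, 1] <- sample(c(-1, 1), n, TRUE)
    if (length(i) > 1) for (m in 2:length(i)) {
      fl <- runif(n) < R[m - 1]
      s[, m] <- ifelse(fl, -s[, m - 1], s[, m - 1])
    }
    X[, i] <- s
  }
  X
}

# brute-force forward-backward oracle: enumerate all 2^M hidden paths of the
# selfed-RIL chain and marginalize exactly
bruteForcePosterior <- function(obs, R, errorRate) {
  M <- length(obs)
  states <- as.matrix(expand.grid(rep(list(c(1L, -1L)), M)))
  emis <- function(o, s) {
    if (is.na(o)) return(1)
    if (o == s) 1 - errorRate else errorRate
  }
  w <- apply(states, 1, function(path) {
    p <- 0.5 * emis(obs[1], path[1])
    if (M > 1) for (m in 2:M) {
      tr <- if (path[m] == path[m - 1]) 1 - R[m - 1] else R[m - 1]
      p <- p * tr * emis(obs[m], path[m])
    }
    p
  })
  w <- w / sum(w)
  t(vapply(seq_len(M), function(m)
    c(sum(w[states[, m] == 1L]), sum(w[states[, m] == -1L])), numeric(2)))
}

# direct V-matrix REML log-likelihood for a single-trial lattice model
# (independent oracle for the MME-based engine)
vRemlLoglik <- function(y, X, Zb, Zg, sb, sg, se) {
  N <- length(y)
  V <- se * diag(N) + sb * tcrossprod(Zb)
  if (!is.null(Zg)) V <- V + sg * tcrossprod(Zg)
  Vi <- solve(V)
  XtVX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtVX, crossprod(X, Vi))
  -0.5 * ((N - ncol(X)) * log(2 * pi) +
          determinant(V, logarithm = TRUE)$modulus[1] +
          determinant(XtVX, logarithm = TRUE)$modulus[1] +
          drop(t(y) %*% P %*% y))
}

# small balanced lattice trial: ng genotypes, J blocks, K reps, one trial
simLattice <- function(ng = 36, J = 6, K = 3, sg = 1, sb = 0.25, se = 1,
                       mu = 50, seed = 1) {
  set.seed(seed)
  g <- rnorm(ng, 0, sqrt(sg))
  ids <- sprintf("G%03d", seq_len(ng))
  rows <- list()
  for (k in seq_len(K)) {
    perm <- sample.int(ng)
    blk <- sort(rep(seq_len(J), length.out = ng))[order(perm)]
    be <- rnorm(J, 0, sqrt(sb))
    rows[[k]] <- data.frame(trial = "T1", rep = k, block = blk,
                            genotype = ids, role = "line",
                            stand = rep(10L, ng),
                            y = mu + g + be[blk] + rnorm(ng, 0, sqrt(se)))
  }
  do.call(rbind, rows)
}
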