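# Dense REML engine on Henderson's mixed-model equations.
#
# Model: y = X beta + Z u + e, u ~ N(0, G(theta)), e ~ N(0, R(theta)) with
# R diagonal (per-group residual variances). The restricted log-likelihood is
# evaluated through the MME coefficient matrix
#   C = [X'R^-1X  X'R^-1Z; Z'R^-1X  Z'R^-1Z + G^-1]
# as -2 lR = (N-p) log(2pi) + log|R| + log|G| + log|C| + y'Py, which equals
# the V-based form log|V| + log|X'V^-1X| + y'Py exactly. Per-residual-group
# crossproducts of W = [X Z] are precomputed once, so each likelihood
# evaluation costs one Cholesky of C.

# buildG(theta) must return list(GinvTriplets = list(i, j, x) on the q x q
# random-effect block (i <= j; off-diagonals are mirrored), logdetG, Rvars).
remlCore <- function(y, X, Z, rGroup, buildG, theta0,
                     lower = -30, upper = 30, reltol = 1e-8) {
  N <- length(y)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("fixed-effects design is rank deficient; aliased: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  q <- ncol(Z)
  W <- cbind(X, Z)
  Lr <- max(rGroup)
  CP <- vector("list", Lr); Wy <- vector("list", Lr)
  yy <- numeric(Lr); nl <- numeric(Lr)
  for (l in seq_len(Lr)) {
    rows <- which(rGroup == l)
    Wl <- W[rows, , drop = FALSE]
    CP[[l]] <- crossprod(Wl)
    Wy[[l]] <- crossprod(Wl, y[rows])
    yy[l] <- sum(y[rows]^2)
    nl[l] <- length(rows)
  }
  ridx <- p + seq_len(q)
  neg2 <- function(theta) {
    g <- buildG(theta)
    Rv <- g$Rvars
    C <- CP[[1]] / Rv[1]
    s <- Wy[[1]] / Rv[1]
    yRy <- yy[1] / Rv[1]
    if (Lr > 1) for (l in 2:Lr) {
      C <- C + CP[[l]] / Rv[l]
      s <- s + Wy[[l]] / Rv[l]
      yRy <- yRy + yy[l] / Rv[l]
    }
    tr <- g$GinvTriplets
    ii <- p + tr$i; jj <- p + tr$j
    C[cbind(ii, jj)] <- C[cbind(ii, jj)] + tr$x
    off <- tr$i != tr$j
    if (any(off))
      C[cbind(jj[off], ii[off])] <- C[cbind(jj[off], ii[off])] + tr$x[off]
    U <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(U)) return(list(val = 1e10))
    chat <- backsolve(U, forwardsolve(t(U), s))
    yPy <- yRy - sum(s * chat)
    val <- (N - p) * log(2 * pi) + sum(nl * log(Rv)) + g$logdetG +
      logdetChol(U) + yPy
    list(val = val, U = U, chat = chat, Rv = Rv)
  }
  obj <- function(theta) neg2(theta)$val
  opt <- nlminb(theta0, obj, lower = lower, upper = upper,
                control = list(rel.tol = reltol, iter.max = 500L,
                               eval.max = 2000L))
  fin <- neg2(opt$par)
  Cinv <- chol2inv(fin$U)
  list(theta = opt$par, logREML = -opt$objective / 2,
       beta = setNames(fin$chat[seq_len(p)], colnames(X)),
       u = setNames(fin$chat[ridx], colnames(Z)),
       Cinv = Cinv, Rvars = fin$Rv, p = p, q = q, N = N,
       convergence = opt$convergence)
}

# indicator matrix for a factor (levels as columns)
indMat <- function(f) {
  f <- droplevels(as.factor(f))
  m <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

# --- G_L covariance structures across trials ---------------------------------
# parameter counts for L environments: ID 1, DIAG L, CS 2, CSH L+1,
# US L(L+1)/2

glNParams <- function(label, L) {
  switch(label, ID = 1L, DIAG = L, CS = 2L, CSH = L + 1L,
         US = as.integer(L * (L + 1) / 2),
         stop("unknown structure: ", label, call. = FALSE))
}

# correlation transform onto (-1/(L-1), 1), keeping CS/CSH matrices psd
rhoTransform <- function(t, L) {
  lo <- -1 / (L - 1) + 1e-6
  lo + (1 - lo) / (1 + exp(-t))
}

glMatrix <- function(label, theta, L) {
  switch(label,
    ID = diag(exp(theta[1]), L),
    DIAG = diag(exp(theta), L),
    CS = {
      v <- exp(theta[1]); rho <- rhoTransform(theta[2], L)
      v * ((1 - rho) * diag(L) + rho)
    },
    CSH = {
      s <- exp(theta[seq_len(L)] / 2); rho <- rhoTransform(theta[L + 1], L)
      Rm <- matrix(rho, L, L); diag(Rm) <- 1
      outer(s, s) * Rm
    },
    US = {
      Lm <- diag(exp(theta[seq_len(L)]), L)
      if (L > 1) Lm[upper.tri(Lm)] <- theta[-seq_len(L)]
      crossprod(Lm)
    })
}

glInit <- function(label, L, v0) {
  lv <- log(v0)
  switch(label,
    ID = lv,
    DIAG = rep(lv, L),
    CS = c(lv, 0.5),
    CSH = c(rep(lv, L), 0.5),
    US = c(rep(lv / 2, L), rep(0, L * (L - 1) / 2)))
}
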