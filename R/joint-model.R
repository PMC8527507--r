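#' Maximum-likelihood fit of the multitrait QTL model
#'
#' Fits y_ei = mu_e + sum_r a_er x_ir + eps_ei with eps_i ~ N(0, Sigma_E) by
#' Haley-Knott regression on expected genotype scores, allowing
#' environment-specific regressor sets (seemingly-unrelated-regression form):
#' iterate (i) a GLS coefficient update given the current Sigma_E and (ii)
#' Sigma_E = residual crossproduct / I, until the log-likelihood changes by
#' less than 1e-10 (at most 200 iterations). When all environments share the
#' same regressor set the solution equals per-environment OLS in one step.
#'
#' @param Y individuals x environments matrix of adjusted means (no missing
#'   cells).
#' @param X individuals x R matrix of genotype scores for the QTLs in the
#'   model (R may be 0).
#' @param active R x E logical: which QTL effects enter which environment's
#'   equation (default all).
#' @return list with \code{mu}, \code{effects} (R x E, exact zeros where
#'   inactive), \code{sigmaE} (ML), \code{logLik}, \code{covB} (GLS
#'   coefficient covariance), \code{coefIndex} (per environment, the stacked
#'   coefficient indices: intercept then active QTL rows) and \code{resid}.
#' @export
fitJointModel <- function(Y, X = NULL, active = NULL) {
  Y <- as.matrix(Y)
  I <- nrow(Y); E <- ncol(Y)
  stopIfNot(!anyNA(Y), "Y must have no missing cells")
  if (is.null(X)) X <- matrix(0, I, 0)
  X <- as.matrix(X)
  R <- ncol(X)
  if (is.null(active)) active <- matrix(TRUE, R, E)
  active <- matrix(active, R, E)
  if (R > 1) {
    cm <- abs(cor(X))
    diag(cm) <- 0
    if (any(cm > 1 - 1e-10)) {
      bad <- which(cm > 1 - 1e-10, arr.ind = TRUE)[1, ]
      stop("degenerate design: QTL columns ", bad[1], " and ", bad[2],
           " are collinear", call. = FALSE)
    }
  }
  # per-environment design matrices
  Ds <- lapply(seq_len(E), function(e)
    cbind(1, X[, active[, e], drop = FALSE]))
  pe <- vapply(Ds, ncol, 1L)
  ptot <- sum(pe)
  stopIfNot(I > max(pe), "insufficient data: more parameters than individuals")
  offs <- cumsum(c(0, pe))[seq_len(E)]
  sameSet <- all(vapply(seq_len(E), function(e)
    identical(active[, e], active[, 1]), TRUE))

  coefIndex <- lapply(seq_len(E), function(e) offs[e] + seq_len(pe[e]))
  fitGLS <- function(Omega) {
    A <- matrix(0, ptot, ptot)
    rhs <- numeric(ptot)
    for (e in seq_len(E)) for (f in seq_len(E)) {
      blk <- Omega[e, f] * crossprod(Ds[[e]], Ds[[f]])
      A[coefIndex[[e]], coefIndex[[f]]] <-
        A[coefIndex[[e]], coefIndex[[f]]] + blk
      rhs[coefIndex[[e]]] <- rhs[coefIndex[[e]]] +
        Omega[e, f] * crossprod(Ds[[e]], Y[, f])
    }
    U <- chol(A)
    beta <- backsolve(U, forwardsolve(t(U), rhs))
    list(beta = beta, Ainv = chol2inv(U))
  }
  residOf <- function(beta) {
    Eres <- Y
    for (e in seq_len(E))
      Eres[, e] <- Y[, e] - Ds[[e]] %*% beta[coefIndex[[e]]]
    Eres
  }
  mvll <- function(S) {
    ld <- determinant(S, logarithm = TRUE)$modulus[1]
    -I / 2 * (E * log(2 * pi) + ld + E)
  }
  # initialize from per-environment OLS, then iterate GLS <-> Sigma updates;
  # with a common regressor set the first GLS step already is the ML solution
  g <- fitGLS(diag(E))
  Eres <- residOf(g$beta)
  sigma <- crossprod(Eres) / I
  ll <- mvll(sigma)
  maxit <- if (sameSet) 1L else 200L
  for (it in seq_len(maxit)) {
    g <- fitGLS(solve(sigma))
    Eres <- residOf(g$beta)
    sigma <- crossprod(Eres) / I
    llNew <- mvll(sigma)
    if (abs(llNew - ll) < 1e-10) { ll <- llNew; break }
    ll <- llNew
  }
  mu <- vapply(seq_len(E), function(e) g$beta[coefIndex[[e]][1]], 0)
  effects <- matrix(0, R, E)
  for (e in seq_len(E)) if (sum(active[, e]))
    effects[active[, e], e] <- g$beta[coefIndex[[e]][-1]]
  list(mu = mu, effects = effects, sigmaE = sigma, logLik = ll,
       covB = g$Ainv, coefIndex = coefIndex, active = active, resid = Eres)
}

# Wald p-values for the active per-environment QTL effects.
# Returns a data.frame(qtl, env, effect, se, p).
jointWald <- function(fit) {
  R <- nrow(fit$active); E <- ncol(fit$active)
  out <- list()
  for (e in seq_len(E)) {
    rows <- which(fit$active[, e])
    if (!length(rows)) next
    idx <- fit$coefIndex[[e]][-1]
    se <- sqrt(diag(fit$covB)[idx])
    a <- fit$effects[rows, e]
    out[[length(out) + 1L]] <- data.frame(
      qtl = rows, env = e, effect = a, se = se,
      p = 2 * pnorm(-abs(a / se)))
  }
  if (!length(out)) return(data.frame(qtl = integer(0), env = integer(0),
                                      effect = numeric(0), se = numeric(0),
                                      p = numeric(0)))
  do.call(rbind, out)
}
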