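## Independent naive oracle implementations, written as direct
## transcriptions (elementwise loops, closed-form linear solves, explicit
## path enumeration) before the package internals. They share no code with
## the package and are deliberately slow; tests run them on small
## instances only.

naiveGip <- function(P, gammaPrime = 1) {
  n <- nrow(P)
  norms2 <- numeric(n)
  for (i in seq_len(n)) norms2[i] <- sum(P[i, ]^2)
  gamma <- gammaPrime / (sum(norms2) / n)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    S[i, j] <- exp(-gamma * sum((P[i, ] - P[j, ])^2))
  S
}

## All-paths enumeration of the decayed ancestor contributions of `target`
## in an edge list (child, parent). Returns a named vector over the
## ancestor closure with the max over paths of delta^length.
naiveDValues <- function(edges, target, delta) {
  D <- c(stats::setNames(1, target))
  walk <- function(node, val) {
    parents <- edges$parent[edges$child == node]
    for (p in parents) {
      v <- val * delta
      if (is.na(D[p]) || v > D[p]) D[p] <<- v
      walk(p, v)
    }
  }
  walk(target, 1)
  D
}

naiveSemantic <- function(edges, targets, delta) {
  dv <- lapply(targets, function(t) naiveDValues(edges, t, delta))
  n <- length(targets)
  S <- matrix(0, n, n, dimnames = list(targets, targets))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(names(dv[[i]]), names(dv[[j]]))
    num <- 0
    for (t in shared) num <- num + dv[[i]][t] + dv[[j]][t]
    S[i, j] <- num / (sum(dv[[i]]) + sum(dv[[j]]))
  }
  S
}

naiveFunctional <- function(DD, LD) {
  nl <- nrow(LD)
  S <- matrix(0, nl, nl)
  for (i in seq_len(nl)) for (j in seq_len(nl)) {
    Di <- which(LD[i, ] == 1)
    Dj <- which(LD[j, ] == 1)
    if (length(Di) == 0 || length(Dj) == 0) { S[i, j] <- 0; next }
    s <- 0
    for (d in Di) s <- s + max(DD[d, Dj])
    for (d in Dj) s <- s + max(DD[d, Di])
    S[i, j] <- s / (length(Di) + length(Dj))
  }
  diag(S) <- 1
  S
}

naiveIntegrate <- function(primary, gip) {
  out <- gip
  for (i in seq_len(nrow(gip))) for (j in seq_len(ncol(gip)))
    if (primary[i, j] != 0) out[i, j] <- primary[i, j]
  out
}

naiveNormalize <- function(S) {
  n <- nrow(S)
  N <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    den <- sum(S[i, ]) + sum(S[, j])
    if (den > 0) N[i, j] <- S[i, j] / den
  }
  N
}

## Fixed point of F = r*N*F + (1-r)*Y by direct linear solve. Used as the
## convergence oracle for the iterative scheme.
naivePropagateClosedForm <- function(N, Y, retention) {
  (1 - retention) * solve(diag(nrow(N)) - retention * N, Y)
}

## The method's own fixed-point iteration, transcribed directly: stop when
## the largest elementwise update falls below 1e-6. (The iteration *is*
## part of the method definition; its agreement with the closed form is
## established separately.)
naivePropagate <- function(N, Y, retention) {
  Fmat <- Y
  repeat {
    Fnew <- retention * N %*% Fmat + (1 - retention) * Y
    if (max(abs(Fnew - Fmat)) < 1e-6) return(Fnew)
    Fmat <- Fnew
  }
}

naivePredict <- function(LD, DD, LL, alpha = 0.9, beta = 0.9,
                         gammaPrime = 1) {
  GL <- naiveGip(LD, gammaPrime)
  GD <- naiveGip(t(LD), gammaPrime)
  LLf <- naiveIntegrate(LL, GL)
  DDf <- naiveIntegrate(DD, GD)
  FL <- naivePropagate(naiveNormalize(LLf), LD, alpha)
  FD <- naivePropagate(naiveNormalize(DDf), t(LD), beta)
  Fe <- (FL + t(FD)) / 2
  nl <- nrow(LD); nd <- ncol(LD)
  LDpl <- matrix(0, nl, nd)
  for (i in seq_len(nl)) for (j in seq_len(nd)) {
    nrm <- sqrt(sum(Fe[, j]^2))
    if (nrm > 0) LDpl[i, j] <- sum(LLf[i, ] * Fe[, j]) / nrm
  }
  LDpd <- matrix(0, nd, nl)
  for (d in seq_len(nd)) for (l in seq_len(nl)) {
    nrm <- sqrt(sum(Fe[l, ]^2))
    if (nrm > 0) LDpd[d, l] <- sum(DDf[d, ] * Fe[l, ]) / nrm
  }
  (LDpl + t(LDpd)) / 2
}

## Brute-force Mann-Whitney AUC: count wins and half-ties over all
## (positive, negative) pairs.
naiveAuc <- function(pos, neg) {
  wins <- 0
  for (p in pos)
    wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

naiveLoocv <- function(LD, DD, LL, alpha = 0.9, beta = 0.9) {
  pos <- which(LD == 1, arr.ind = TRUE)
  posScores <- numeric(nrow(pos))
  negScores <- NULL
  for (k in seq_len(nrow(pos))) {
    train <- LD
    train[pos[k, 1], pos[k, 2]] <- 0
    sc <- naivePredict(train, DD, LL, alpha, beta)
    posScores[k] <- sc[pos[k, 1], pos[k, 2]]
    negScores <- c(negScores, sc[LD == 0])
  }
  naiveAuc(posScores, negScores)
}
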