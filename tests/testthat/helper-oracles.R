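# Independent oracles used across the suite.  These deliberately avoid the
# package's own pruning/ODE code paths: transition probabilities come from
# an accurate matrix exponential, likelihoods from explicit sums over internal-state
# assignments, birth-death factors from the closed-form solution of the
# extinction/data equations, and SSE likelihoods from deSolve integration.

# accurate reference matrix exponential (scaling-and-squaring via Matrix;
# ape::matexpo is unreliable for dense non-symmetric generators)
expm_o <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M)))

# brute-force Mk / joint-chain likelihood by enumeration over all
# internal-node state assignments; tip_states are 1-based integers
enum_mk_loglik <- function(tree, tip_states, Q, prior) {
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge; el <- tr$edge.length
  k <- nrow(Q); ntip <- length(tr$tip.label)
  nn <- max(edge)
  P <- lapply(seq_len(nrow(edge)), function(e) expm_o(Q * el[e]))
  internal <- setdiff(seq_len(nn), seq_len(ntip))
  grid <- expand.grid(rep(list(seq_len(k)), length(internal)))
  root <- edge[nrow(edge), 1]
  tot <- 0
  x <- tip_states[tr$tip.label]
  for (r in seq_len(nrow(grid))) {
    st <- integer(nn)
    st[seq_len(ntip)] <- x
    st[internal] <- as.integer(grid[r, ])
    pr <- prior[st[root]]
    for (e in seq_len(nrow(edge)))
      pr <- pr * P[[e]][st[edge[e, 1]], st[edge[e, 2]]]
    tot <- tot + pr
  }
  log(tot)
}

# brute-force minimum parsimony changes by enumeration
enum_parsimony <- function(tree, tip_states, k) {
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge; ntip <- length(tr$tip.label)
  nn <- max(edge)
  internal <- setdiff(seq_len(nn), seq_len(ntip))
  grid <- expand.grid(rep(list(seq_len(k)), length(internal)))
  x <- tip_states[tr$tip.label]
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    st <- integer(nn)
    st[seq_len(ntip)] <- x
    st[internal] <- as.integer(grid[r, ])
    ch <- sum(st[edge[, 1]] != st[edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# closed-form constant-rate birth-death likelihood with sampling fraction,
# FitzJohn-free (single state) and conditioned on survival of both root
# lineages; matches the SSE tip/root conventions
bd_loglik_closed <- function(tree, lambda, mu, f = 1, cond = TRUE) {
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge; el <- tr$edge.length
  nn <- max(edge); ntip <- length(tr$tip.label)
  E <- numeric(nn); D <- numeric(nn); nch <- integer(nn)
  lsc <- 0
  E[1:ntip] <- 1 - f; D[1:ntip] <- f
  r <- lambda - mu
  stopifnot(abs(r) > 1e-12)
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]; t <- el[e]
    G0 <- 1 - E[ch]
    den <- r + lambda * G0 * (exp(r * t) - 1)
    E1 <- 1 - r * exp(r * t) * G0 / den
    Psi <- exp(r * t) * r^2 / den^2
    Dv <- D[ch] * Psi
    if (nch[p] == 0) { D[p] <- Dv; E[p] <- E1 }
    else D[p] <- D[p] * Dv * lambda
    nch[p] <- nch[p] + 1
    if (D[p] < 1e-200) { D[p] <- D[p] * 1e200; lsc <- lsc - log(1e200) }
  }
  root <- edge[nrow(edge), 1]
  lik <- D[root]
  if (cond) lik <- lik / (lambda * (1 - E[root])^2)
  log(lik) + lsc
}

# fine-tolerance deSolve integration of the SSE equations (FitzJohn root,
# conditioned on survival); tip_states are 1-based integers
sse_ode_oracle <- function(tree, tip_states, lambda, mu, Q, f = 1) {
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge; el <- tr$edge.length
  k <- length(lambda); nn <- max(edge); ntip <- length(tr$tip.label)
  Ei <- matrix(0, nn, k); Di <- matrix(0, nn, k)
  nch <- integer(nn); lsc <- 0
  x <- tip_states[tr$tip.label]
  for (i in 1:ntip) { Ei[i, ] <- 1 - f; Di[i, x[i]] <- f }
  qq <- Q; diag(qq) <- 0; qrow <- rowSums(qq)
  deriv <- function(t, y, parms) {
    E <- y[1:k]; D <- y[(k + 1):(2 * k)]
    dE <- mu - (lambda + mu + qrow) * E + lambda * E^2 + qq %*% E
    dD <- -(lambda + mu + qrow) * D + 2 * lambda * E * D + qq %*% D
    list(c(dE, dD))
  }
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    y0 <- c(Ei[ch, ], Di[ch, ])
    out <- deSolve::ode(y0, c(0, el[e]), deriv, NULL, method = "ode45",
                        rtol = 1e-11, atol = 1e-11)
    y1 <- out[nrow(out), -1]
    E1 <- y1[1:k]; D1 <- y1[(k + 1):(2 * k)]
    mx <- max(D1); lsc <- lsc + log(mx); D1 <- D1 / mx
    if (nch[p] == 0) { Di[p, ] <- D1; Ei[p, ] <- E1 }
    else Di[p, ] <- Di[p, ] * D1 * lambda
    nch[p] <- nch[p] + 1
  }
  root <- edge[nrow(edge), 1]
  Dr <- Di[root, ]; Er <- Ei[root, ]
  w <- Dr / sum(Dr)
  log(sum(w * Dr / (lambda * (1 - Er)^2))) + lsc
}

# dependent-model generator built independently of the package internals;
# rate order q12, q13, q21, q24, q31, q34, q42, q43 over joint states
# 1 = (0,0), 2 = (0,1), 3 = (1,0), 4 = (1,1)
oracle_q_dep <- function(r) {
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- r[1]; Q[1, 3] <- r[2]; Q[2, 1] <- r[3]; Q[2, 4] <- r[4]
  Q[3, 1] <- r[5]; Q[3, 4] <- r[6]; Q[4, 2] <- r[7]; Q[4, 3] <- r[8]
  diag(Q) <- -rowSums(Q)
  Q
}

oracle_q_er <- function(rate, k) {
  Q <- matrix(rate, k, k); diag(Q) <- 0; diag(Q) <- -rowSums(Q); Q
}

# random ultrametric tree (coalescent shape) with unit-scale depth
rand_tree <- function(n) {
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}
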