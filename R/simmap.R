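# Stochastic character mapping: joint node-state sampling followed by
# endpoint-conditioned branch histories (rejection sampling with a
# uniformization fallback).

# Sample an endpoint-conditioned CTMC path on one branch by rejection
# sampling of forward paths; uniformization fallback guarantees
# termination.  Returns list(times, states): sojourn entry times measured
# from the rootward end (first entry (0, a)).
.branch_history_reject <- function(Q, t, a, b, max_reject = 1e4) {
  k <- nrow(Q)
  out_rate <- -diag(Q)
  if (t <= 0 || max(out_rate) <= 0) {
    if (a != b) stop("state change across a zero-length or rate-zero branch")
    return(list(times = 0, states = a))
  }
  for (rep in seq_len(max_reject)) {
    s <- a; tt <- 0
    times <- 0; states <- a
    repeat {
      r <- out_rate[s]
      if (r <= 0) break
      w <- rexp(1, r)
      if (tt + w > t) break
      tt <- tt + w
      p <- Q[s, ]; p[s] <- 0
      s <- sample.int(k, 1, prob = p)
      times <- c(times, tt); states <- c(states, s)
    }
    if (s == b) return(list(times = times, states = states))
  }
  .branch_history_unif(Q, t, a, b)
}

# Uniformization: sample the number of jumps of the uniformized chain
# conditional on the endpoints, place them uniformly, sample the bridge,
# then drop virtual (self) jumps.
.branch_history_unif <- function(Q, t, a, b, nmax = 10000L) {
  k <- nrow(Q)
  om <- max(-diag(Q)) * 1.05 + 1e-12
  R <- diag(k) + Q / om
  Pt <- mk_pmat_cpp(Q, t)
  denom <- Pt[a, b]
  if (denom <= 0) stop("impossible endpoint pair in uniformization")
  # P(N = n | a, b) proportional to Pois(om t; n) * R^n[a, b]
  Rpow <- list(diag(k))
  probs <- numeric(0)
  lpois <- function(n) -om * t + n * log(om * t) - lgamma(n + 1)
  cum <- 0
  n <- 0
  while (n < nmax) {
    Rn <- Rpow[[n + 1]]
    pr <- exp(lpois(n)) * Rn[a, b] / denom
    probs <- c(probs, pr)
    cum <- cum + pr
    if (cum > 1 - 1e-12 && n >= 1) break
    Rpow[[n + 2]] <- Rpow[[n + 1]] %*% R
    n <- n + 1
  }
  N <- sample.int(length(probs), 1, prob = probs) - 1L
  if (N == 0) return(list(times = 0, states = a))
  jt <- sort(runif(N, 0, t))
  states <- integer(N)
  prev <- a
  for (i in seq_len(N)) {
    rem <- N - i  # jumps after this one
    w <- R[prev, ] * Rpow[[rem + 1]][, b]
    states[i] <- sample.int(k, 1, prob = w)
    prev <- states[i]
  }
  keep_t <- 0; keep_s <- a; cur <- a
  for (i in seq_len(N)) {
    if (states[i] != cur) {
      keep_t <- c(keep_t, jt[i]); keep_s <- c(keep_s, states[i])
      cur <- states[i]
    }
  }
  list(times = keep_t, states = keep_s)
}

#' Sample stochastic character maps
#'
#' Draws full character histories consistent with the tip data: joint node
#' states are sampled exactly from their conditional distribution
#' (backward filtering, forward sampling), then each branch history is
#' drawn by rejection sampling of forward CTMC paths, falling back to
#' uniformization after `max_reject` rejections so termination is
#' guaranteed.  Summaries report per-node and per-edge posterior state
#' frequencies and per-map change counts.
#'
#' @param tree A `phylo` object.
#' @param tip_states Named state vector over the tips (NA = ambiguous).
#' @param model An [mk_model()].
#' @param n_maps Number of maps (the conventional choice is 1000).
#' @param seed Optional RNG seed.
#' @param max_reject Rejection-sampling cap per branch before switching to
#'   uniformization.
#' @return Object of class `stochastic_map_set`: `node_freq` (nodes x
#'   states), `edge_freq` (expected fraction of time per state on each
#'   edge), `changes` (n_maps x k^2 transition-count matrix with columns
#'   `"i->j"`), `n_maps`, `states`, and `maps` (per-map edge histories).
#' @export
sample_stochastic_maps <- function(tree, tip_states, model, n_maps = 1000,
                                   seed = NULL, max_reject = 1e4) {
  .with_seed(seed, {
    td <- .tree_prep(tree)
    k <- length(model$states)
    ntip <- td$ntip
    L <- .tip_lik_matrix(tip_states, td$tree$tip.label, model$states)
    rs <- .root_spec(model$root_policy, Q = model$Q,
                     prior = model$root_prior, k = k)
    res <- mk_pruning_cpp(td$edge, td$el, L, model$Q, rs$mode, rs$prior,
                          return_partials = TRUE)
    if (!is.finite(res$loglik)) stop("data impossible under supplied model")
    D <- res$partials
    edge <- td$edge; el <- td$el
    nE <- nrow(edge)
    nnode <- max(edge)
    root <- edge[nE, 1]
    P <- lapply(seq_len(nE), function(e) mk_pmat_cpp(model$Q, el[e]))
    prior <- switch(as.character(rs$mode),
                    "0" = rep(1 / k, k),
                    "1" = { s <- D[root, ]; s / sum(s) },
                    "2" = rs$prior)
    node_cnt <- matrix(0, nnode, k)
    edge_time <- matrix(0, nE, k)
    changes <- matrix(0L, n_maps, k * k)
    colnames(changes) <- as.vector(outer(seq_len(k), seq_len(k),
                                         function(i, j) paste0(i, "->", j)))
    maps <- vector("list", n_maps)
    for (mmap in seq_len(n_maps)) {
      st <- integer(nnode)
      w <- prior * D[root, ]
      st[root] <- sample.int(k, 1, prob = w)
      for (e in rev(seq_len(nE))) {  # preorder
        par <- edge[e, 1]; ch <- edge[e, 2]
        w <- P[[e]][st[par], ] * D[ch, ]
        st[ch] <- sample.int(k, 1, prob = w)
      }
      node_cnt[cbind(seq_len(nnode), st)] <-
        node_cnt[cbind(seq_len(nnode), st)] + 1
      hist_e <- vector("list", nE)
      cc <- matrix(0L, k, k)
      for (e in seq_len(nE)) {
        h <- .branch_history_reject(model$Q, el[e], st[edge[e, 1]],
                                    st[edge[e, 2]], max_reject)
        hist_e[[e]] <- h
        ns <- length(h$states)
        if (ns > 1)
          for (i in 2:ns)
            cc[h$states[i - 1], h$states[i]] <-
              cc[h$states[i - 1], h$states[i]] + 1L
        bounds <- c(h$times, el[e])
        for (i in seq_len(ns))
          edge_time[e, h$states[i]] <- edge_time[e, h$states[i]] +
            (bounds[i + 1] - bounds[i])
      }
      changes[mmap, ] <- as.vector(cc)
      maps[[mmap]] <- hist_e
    }
    node_freq <- node_cnt / n_maps
    colnames(node_freq) <- model$states
    tot <- pmax(el, .Machine$double.eps)
    edge_freq <- edge_time / (n_maps * tot)
    colnames(edge_freq) <- model$states
    structure(list(node_freq = node_freq, edge_freq = edge_freq,
                   changes = changes, n_maps = n_maps,
                   states = model$states, maps = maps,
                   tree = td$tree, edge = edge, seed = seed),
              class = "stochastic_map_set")
  })
}
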