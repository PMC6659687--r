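# Mk likelihoods, model fitting, marginal ancestral states, parsimony,
# and origin/loss counting for discrete characters on a time tree.

#' Construct an Mk model
#'
#' @param states Ordered state labels (e.g. `c("0", "1")`).
#' @param Q Generator matrix (off-diagonals >= 0, rows sum to 0); or supply
#'   `rate` for an equal-rates model.
#' @param rate Single rate for an ER model (ignored if `Q` given).
#' @param model_class `"ER"`, `"ARD"` or `"custom"` (bookkeeping only).
#' @param root_policy Root state prior: `"uniform"` (default, matching the
#'   usual ancestral-state convention), `"stationary"`, `"fitzjohn"` or
#'   `"given"` (with `root_prior`).
#' @param root_prior Probability vector over states when
#'   `root_policy = "given"`.
#' @return An object of class `mk_model`.
#' @export
mk_model <- function(states, Q = NULL, rate = NULL,
                     model_class = c("custom", "ER", "ARD"),
                     root_policy = c("uniform", "stationary", "fitzjohn",
                                     "given"),
                     root_prior = NULL) {
  model_class <- match.arg(model_class)
  root_policy <- match.arg(root_policy)
  states <- as.character(states)
  k <- length(states)
  if (is.null(Q)) {
    if (is.null(rate)) stop("supply either Q or rate")
    Q <- .q_er(rate, k)
    model_class <- "ER"
  }
  .validate_generator(Q)
  if (nrow(Q) != k) stop("Q dimension does not match number of states")
  dimnames(Q) <- list(states, states)
  structure(list(states = states, Q = Q, model_class = model_class,
                 root_policy = root_policy, root_prior = root_prior),
            class = "mk_model")
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' Per-branch transition probabilities are matrix exponentials of the
#' generator; partial likelihoods are rescaled at each node with
#' accumulated log factors, so the result is stable on large trees.
#' Missing (`NA`) tip states are treated as fully ambiguous.
#'
#' @param tree A `phylo` object.
#' @param tip_states Named vector of states over the tips (NA = ambiguous).
#' @param model An [mk_model()].
#' @return Log-likelihood (scalar; `-Inf` flags impossible data).
#' @export
mk_loglik <- function(tree, tip_states, model) {
  td <- .tree_prep(tree)
  L <- .tip_lik_matrix(tip_states, td$tree$tip.label, model$states)
  rs <- .root_spec(model$root_policy, Q = model$Q, prior = model$root_prior,
                   k = length(model$states))
  mk_pruning_cpp(td$edge, td$el, L, model$Q, rs$mode, rs$prior)$loglik
}

#' Fit ER and ARD Mk models by maximum likelihood
#'
#' Bounded multistart optimisation of the log-likelihood over transition
#' rates; the equal-rates (ER, one free rate) and all-rates-different
#' (ARD, k(k-1) free rates) models are both fitted and compared by AIC.
#'
#' @param tree A `phylo` object.
#' @param tip_states Named state vector over the tips.
#' @param states State labels; defaults to the sorted observed states.
#' @param root_policy Root prior policy (see [mk_model()]).
#' @param bounds Rate search bounds (per-unit-branch-length).
#' @param n_starts Number of optimiser restarts for ARD.
#' @param seed Seed for the (log-uniform) restart draws.
#' @return A list of class `mk_fit`: fitted `er` and `ard` models with
#'   log-likelihoods, an `aic` table, and `best` / `model` for the
#'   AIC-selected model.
#' @export
fit_mk_ml <- function(tree, tip_states, states = NULL,
                      root_policy = "uniform", bounds = c(1e-8, 1e3),
                      n_starts = 5, seed = 1) {
  if (is.null(states))
    states <- sort(unique(as.character(tip_states[!is.na(tip_states)])))
  k <- length(states)
  td <- .tree_prep(tree)
  if (k < 2) {
    warning("fewer than 2 observed states; rates unidentifiable, returning ",
            "rate 0")
    mod <- mk_model(states = if (k) states else "0", rate = 0,
                    root_policy = root_policy)
    return(structure(list(er = list(model = mod, rate = 0, loglik = 0,
                                    aic = 2),
                          ard = NULL,
                          aic = data.frame(model = "ER", df = 1,
                                           loglik = 0, aic = 2),
                          best = "ER", model = mod),
                     class = "mk_fit"))
  }
  L <- .tip_lik_matrix(tip_states, td$tree$tip.label, states)
  nll <- function(logrates, builder) {
    Q <- builder(exp(logrates))
    rs <- .root_spec(root_policy, Q = Q, k = k)
    ll <- mk_pruning_cpp(td$edge, td$el, L, Q, rs$mode, rs$prior)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  lb <- log(bounds[1]); ub <- log(bounds[2])
  # ER: 1-D search
  er_b <- function(r) .q_er(r[1], k)
  er_opt <- stats::optimize(function(lr) nll(lr, er_b), c(lb, ub))
  er_rate <- exp(er_opt$minimum)
  er_ll <- -er_opt$objective
  # ARD: multistart L-BFGS-B
  np <- k * (k - 1)
  ard_b <- function(r) .q_ard(r, k)
  starts <- .with_seed(seed, {
    s <- matrix(runif(np * n_starts, lb / 4, ub / 8), n_starts, np)
    s[1, ] <- log(er_rate)  # ER solution is always one start
    s
  })
  best <- NULL
  for (i in seq_len(n_starts)) {
    o <- tryCatch(
      stats::optim(starts[i, ], nll, builder = ard_b, method = "L-BFGS-B",
                   lower = lb, upper = ub,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("ARD optimisation failed in all restarts")
  ard_rates <- exp(best$par)
  ard_ll <- -best$value
  er_model <- mk_model(states, Q = .q_er(er_rate, k), model_class = "ER",
                       root_policy = root_policy)
  ard_model <- mk_model(states, Q = .q_ard(ard_rates, k),
                        model_class = "ARD", root_policy = root_policy)
  aic <- data.frame(model = c("ER", "ARD"), df = c(1, np),
                    loglik = c(er_ll, ard_ll),
                    aic = c(2 * 1 - 2 * er_ll, 2 * np - 2 * ard_ll))
  sel <- aic$model[which.min(aic$aic)]
  structure(list(
    er = list(model = er_model, rate = er_rate, loglik = er_ll,
              aic = aic$aic[1]),
    ard = list(model = ard_model, rates = ard_rates, loglik = ard_ll,
               aic = aic$aic[2]),
    aic = aic, best = sel,
    model = if (sel == "ER") er_model else ard_model),
    class = "mk_fit")
}

#' Marginal ancestral state probabilities
#'
#' Exact per-node marginal posteriors under the supplied Mk model, computed
#' by a two-pass (inside/outside) algorithm equivalent to rerooting at
#' every node.  Each node's probability vector sums to one.
#'
#' @param tree A `phylo` object.
#' @param tip_states Named state vector over the tips.
#' @param model An [mk_model()] (typically the AIC-selected fit).
#' @return Object of class `ancestral_reconstruction`: list with `prob`
#'   (matrix, rows = all nodes in ape numbering, columns = states),
#'   `loglik`, `model`, `tip_states`.
#' @export
marginal_ancestral_states <- function(tree, tip_states, model) {
  td <- .tree_prep(tree)
  k <- length(model$states)
  ntip <- td$ntip
  L <- .tip_lik_matrix(tip_states, td$tree$tip.label, model$states)
  rs <- .root_spec(model$root_policy, Q = model$Q, prior = model$root_prior,
                   k = k)
  res <- mk_pruning_cpp(td$edge, td$el, L, model$Q, rs$mode, rs$prior,
                        return_partials = TRUE)
  if (!is.finite(res$loglik)) stop("data impossible under supplied model")
  D <- res$partials
  nnode <- nrow(D)
  edge <- td$edge; el <- td$el
  # per-edge child contributions P(t) %*% D_child (normalised)
  contrib <- vector("list", nrow(edge))
  P <- vector("list", nrow(edge))
  for (e in seq_len(nrow(edge))) {
    P[[e]] <- mk_pmat_cpp(model$Q, el[e])
    v <- as.vector(P[[e]] %*% D[edge[e, 2], ])
    contrib[[e]] <- v / max(v)
  }
  root <- edge[nrow(edge), 1]
  prior <- switch(as.character(rs$mode),
                  "0" = rep(1 / k, k),
                  "1" = { s <- D[root, ]; s / sum(s) },
                  "2" = rs$prior)
  U <- matrix(NA_real_, nnode, k)
  U[root, ] <- prior
  children <- split(seq_len(nrow(edge)), edge[, 1])
  for (e in rev(seq_len(nrow(edge)))) {  # preorder
    par <- edge[e, 1]; ch <- edge[e, 2]
    sibs <- setdiff(children[[as.character(par)]], e)
    above <- U[par, ]
    for (s in sibs) above <- above * contrib[[s]]
    u <- as.vector(crossprod(P[[e]], above))
    U[ch, ] <- u / max(u)
  }
  prob <- D * U
  prob <- prob / rowSums(prob)
  colnames(prob) <- model$states
  structure(list(prob = prob, loglik = res$loglik, model = model,
                 tree = td$tree,
                 tip_states = tip_states[td$tree$tip.label]),
            class = "ancestral_reconstruction")
}

#' Fitch parsimony counts and MPR state sets
#'
#' Fitch down-pass minimum change count with the standard up-pass giving
#' each node's most-parsimonious-reconstruction state set.  Missing tips
#' are treated as fully ambiguous.
#'
#' @param tree A `phylo` object (binary).
#' @param tip_states Named state vector over the tips.
#' @param states State labels; defaults to sorted observed states.
#' @return List of class `parsimony_reconstruction`: `count` (minimum
#'   changes) and `node_sets` (logical matrix, all nodes x states).
#' @export
fitch_parsimony <- function(tree, tip_states, states = NULL) {
  if (is.null(states))
    states <- sort(unique(as.character(tip_states[!is.na(tip_states)])))
  k <- length(states)
  td <- .tree_prep(tree)
  ntip <- td$ntip
  edge <- td$edge
  nnode <- max(edge)
  S <- matrix(FALSE, nnode, k)  # preliminary sets
  x <- tip_states[td$tree$tip.label]
  for (i in seq_len(ntip)) {
    if (is.na(x[i])) S[i, ] <- TRUE
    else S[i, match(as.character(x[i]), states)] <- TRUE
  }
  children <- split(edge[, 2], edge[, 1])
  count <- 0L
  ord <- unique(edge[, 1])  # postorder parents
  for (p in ord) {
    ch <- children[[as.character(p)]]
    acc <- S[ch[1], ]
    for (c2 in ch[-1]) {
      inter <- acc & S[c2, ]
      if (any(inter)) acc <- inter
      else { acc <- acc | S[c2, ]; count <- count + 1L }
    }
    S[p, ] <- acc
  }
  # up-pass (MPR final sets, binary trees)
  Fset <- S
  root <- edge[nrow(edge), 1]
  Fset[root, ] <- S[root, ]
  for (e in rev(seq_len(nrow(edge)))) {
    p <- edge[e, 1]; v <- edge[e, 2]
    if (v <= ntip) next
    Fp <- Fset[p, ]; Pv <- S[v, ]
    if (all(!Fp | Pv)) {  # F(parent) contained in P(v)
      Fset[v, ] <- Fp
    } else {
      ch <- children[[as.character(v)]]
      un <- rep(FALSE, k)
      for (c2 in ch) un <- un | S[c2, ]
      inter_empty <- !any(Reduce(`&`, lapply(ch, function(c2) S[c2, ])))
      if (inter_empty) Fset[v, ] <- Pv | Fp
      else Fset[v, ] <- Pv | (Fp & un)
    }
  }
  colnames(Fset) <- states
  structure(list(count = count, node_sets = Fset, states = states,
                 tree = td$tree),
            class = "parsimony_reconstruction")
}

#' Count trait origins and losses
#'
#' For a maximum-likelihood [marginal_ancestral_states()] reconstruction of
#' a binary trait, each internal node is assigned its maximum-probability
#' state (ties broken toward absence, the conservative choice) and the
#' parent-to-child edges showing 0 to 1 (gain) and 1 to 0 (loss) changes
#' are counted.  For a [sample_stochastic_maps()] set, the posterior mean
#' gain and loss counts across maps are returned.
#'
#' @param x An `ancestral_reconstruction` or `stochastic_map_set`.
#' @return Named numeric vector `c(gains, losses)`.
#' @export
count_origins <- function(x) UseMethod("count_origins")

#' @export
count_origins.ancestral_reconstruction <- function(x) {
  tree <- x$tree
  ntip <- length(tree$tip.label)
  k <- ncol(x$prob)
  if (k != 2) stop("origin counting expects a binary trait")
  st <- integer(max(tree$edge))
  # ties -> state 1 (absence) via which.max on reversed comparison
  node_state <- ifelse(x$prob[, 2] > x$prob[, 1], 2L, 1L)
  st <- node_state
  obs <- x$tip_states
  for (i in seq_len(ntip))
    if (!is.na(obs[i])) st[i] <- match(as.character(obs[i]), colnames(x$prob))
  gains <- 0L; losses <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    a <- st[tree$edge[e, 1]]; b <- st[tree$edge[e, 2]]
    if (a == 1L && b == 2L) gains <- gains + 1L
    if (a == 2L && b == 1L) losses <- losses + 1L
  }
  c(gains = gains, losses = losses)
}

#' @export
count_origins.stochastic_map_set <- function(x) {
  if (length(x$states) != 2) stop("origin counting expects a binary trait")
  c(gains = mean(x$changes[, "1->2"]), losses = mean(x$changes[, "2->1"]))
}
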