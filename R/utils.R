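# Internal helpers shared across modules.

# Postorder edge representation consumed by the C++ kernels.
.tree_prep <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a \"phylo\" object")
  if (is.null(tree$edge.length)) stop("tree has no edge lengths")
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = tr$edge, el = tr$edge.length,
       ntip = length(tr$tip.label), tree = tr)
}

# Tip partial-likelihood matrix in tip-index order.  `tip_states` is a
# named vector over (at least) all tip labels; NA means fully ambiguous.
.tip_lik_matrix <- function(tip_states, tip_labels, states) {
  k <- length(states)
  miss <- setdiff(tip_labels, names(tip_states))
  if (length(miss))
    stop("tip states missing for: ", paste(miss, collapse = ", "))
  x <- tip_states[tip_labels]
  L <- matrix(0, length(tip_labels), k)
  for (i in seq_along(x)) {
    if (is.na(x[i])) {
      L[i, ] <- 1
    } else {
      j <- match(as.character(x[i]), as.character(states))
      if (is.na(j))
        stop("tip state '", x[i], "' not among model states (",
             paste(states, collapse = ", "), ")")
      L[i, j] <- 1
    }
  }
  L
}

# Map a root policy to the (mode, prior) pair used by the C++ kernels.
.root_spec <- function(policy, Q = NULL, prior = NULL, k = NULL) {
  policy <- match.arg(policy, c("uniform", "fitzjohn", "stationary", "given"))
  if (policy == "uniform") return(list(mode = 0L, prior = numeric(k)))
  if (policy == "fitzjohn") return(list(mode = 1L, prior = numeric(k)))
  if (policy == "given") {
    stopifnot(!is.null(prior), abs(sum(prior) - 1) < 1e-8)
    return(list(mode = 2L, prior = as.numeric(prior)))
  }
  # stationary distribution: left null vector of Q
  stopifnot(!is.null(Q))
  ns <- nrow(Q)
  A <- rbind(t(Q), rep(1, ns))
  pi <- qr.solve(A, c(numeric(ns), 1))
  pi <- pmax(pi, 0); pi <- pi / sum(pi)
  list(mode = 2L, prior = pi)
}

# Equal-rates / all-rates-different generator constructors.
.q_er <- function(rate, k) {
  Q <- matrix(rate, k, k); diag(Q) <- 0; diag(Q) <- -rowSums(Q); Q
}
.q_ard <- function(rates, k) {
  Q <- matrix(0, k, k)
  Q[row(Q) != col(Q)] <- rates  # column-major over off-diagonal cells
  diag(Q) <- -rowSums(Q)
  Q
}

.validate_generator <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop("Q must be square")
  off <- Q[row(Q) != col(Q)]
  if (any(off < 0)) stop("off-diagonal rates must be >= 0")
  if (any(abs(rowSums(Q)) > 1e-8 * max(1, max(abs(Q)))))
    stop("generator rows must sum to zero")
  invisible(Q)
}

# Effective sample size by initial positive sequence of autocovariances.
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 2, 2000), plot = FALSE)$acf[-1]
  s <- 0
  for (t in seq(1, length(ac) - 1, by = 2)) {
    pair <- ac[t] + ac[t + 1]
    if (is.na(pair) || pair <= 0) break
    s <- s + pair
  }
  max(1, n / (1 + 2 * s))
}

.logmeanexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

# Run `expr` with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
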