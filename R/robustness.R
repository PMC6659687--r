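# Safeguards against SSE false positives: a nonparametric tip-rate test
# on inverse equal-splits statistics, and parametric-bootstrap
# calibration of the likelihood-ratio p value for trait-dependent
# diversification.

#' Inverse equal-splits tip rates
#'
#' For each tip, the equal-splits statistic is the root-ward sum
#' `ES = sum_j l_j / 2^(j-1)` with j = 1 at the terminal edge; its inverse
#' 1/ES (per Myr) is a nonparametric proxy for the tip's speciation rate.
#' Tips subtended by zero-length terminal edges are flagged and excluded
#' from group means.
#'
#' @param tree A `phylo` object with positive terminal edges.
#' @return Data frame of class `tip_rate_table`: tip, `es` (Myr), `rate`
#'   (1/Myr, NA when flagged), `flagged`.
#' @export
inverse_equal_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  parent_edge <- match(seq_len(max(edge)), edge[, 2])  # edge above node
  root <- ntip + 1L
  es <- numeric(ntip)
  flagged <- logical(ntip)
  for (i in seq_len(ntip)) {
    node <- i; j <- 0; s <- 0
    while (node != root) {
      e <- parent_edge[node]
      j <- j + 1
      s <- s + tree$edge.length[e] / 2^(j - 1)
      node <- edge[e, 1]
    }
    es[i] <- s
    flagged[i] <- tree$edge.length[parent_edge[i]] <= 0
  }
  out <- data.frame(tip = tree$tip.label, es = es,
                    rate = ifelse(flagged | es <= 0, NA_real_, 1 / es),
                    flagged = flagged, stringsAsFactors = FALSE)
  class(out) <- c("tip_rate_table", class(out))
  out
}

#' Nonparametric tip-rate test of state-dependent speciation
#'
#' The observed statistic is the difference in mean inverse equal-splits
#' rate between state-1 and state-0 tips.  Its null distribution is built
#' by simulating the binary character `n_sim` times on the same tree under
#' the equal-rates Mk model fitted to the observed trait; the two-tailed
#' p value uses the +1 small-sample correction (doubled smaller tail,
#' capped at 1).
#'
#' @param tree A `phylo` object.
#' @param tip_states Named 0/1 vector over the tips (both states present).
#' @param n_sim Number of null simulations (default 1000).
#' @param seed Optional RNG seed.
#' @param max_redraw Cap on redraws of monomorphic null traits.
#' @return Object of class `fisse_result`: `statistic` (observed mean-rate
#'   difference, state 1 minus state 0), `null` (null statistics), `p`,
#'   `rate` (fitted ER rate), `redraws`.
#' @export
fisse_test <- function(tree, tip_states, n_sim = 1000, seed = NULL,
                       max_redraw = 100 * n_sim) {
  x <- tip_states[tree$tip.label]
  if (any(is.na(x))) stop("NA tip states; prune unscored species first")
  if (length(unique(x)) < 2) stop("both states must be present among tips")
  ert <- inverse_equal_splits(tree)
  rate_of <- function(states) {
    r1 <- mean(ert$rate[states == 1], na.rm = TRUE)
    r0 <- mean(ert$rate[states == 0], na.rm = TRUE)
    r1 - r0
  }
  obs <- rate_of(x)
  fit <- fit_mk_ml(tree, setNames(as.character(x), names(x)),
                   states = c("0", "1"))
  er_rate <- fit$er$rate
  Q <- .q_er(er_rate, 2)
  .with_seed(seed, {
    null_stats <- numeric(n_sim)
    redraws <- 0L
    for (i in seq_len(n_sim)) {
      repeat {
        root <- sample.int(2, 1)  # ER stationary distribution is uniform
        sim <- simulate_mk_trait(tree, Q, root_state = root)
        st <- sim$tip_states - 1L
        if (length(unique(st)) == 2) break
        redraws <- redraws + 1L
        if (redraws > max_redraw)
          stop("could not obtain polymorphic null traits")
      }
      null_stats[i] <- rate_of(st[tree$tip.label])
    }
    lo <- (1 + sum(null_stats <= obs)) / (n_sim + 1)
    hi <- (1 + sum(null_stats >= obs)) / (n_sim + 1)
    p <- min(1, 2 * min(lo, hi))
    structure(list(statistic = obs, null = null_stats, p = p,
                   rate = er_rate, redraws = redraws, n_sim = n_sim,
                   seed = seed),
              class = "fisse_result")
  })
}

#' Parametric-bootstrap calibration of the diversification LRT
#'
#' Given the real tree and a binary trait, the trait is re-simulated
#' `n_rep` times under the Mk transition rates fitted to the observed data
#' (starting from the reconstructed ancestral state, absence by default).
#' For each replicate the equal-rates diversification model
#' (lambda0 = lambda1, mu0 = mu1) is tested against the free model by a
#' likelihood-ratio chi-square, and the resulting null p values give an
#' empirical significance cutoff: the nearest-rank 5th percentile.
#' Observed significance requires the real-data p value to fall below
#' that cutoff, guarding against the inflated type-I error of naive
#' state-dependent diversification tests.
#'
#' @param tree Ultrametric `phylo`.
#' @param trait Named 0/1 vector over the tips.
#' @param rates Optional 2x2 generator for the simulating chain; defaults
#'   to the ER maximum-likelihood fit on the observed trait (gains-only
#'   simulation available via `gains_only`).
#' @param root_state Simulation root state (default `"0"`, trait absence).
#' @param n_rep Number of simulated traits (default 100).
#' @param percentile Significance level defining the cutoff (default
#'   0.05; nearest-rank convention).
#' @param f Sampling fraction passed to the diversification fits.
#' @param gains_only Zero the loss rate of the simulating chain.
#' @param seed Optional RNG seed.
#' @param n_starts Optimiser restarts per replicate fit.
#' @param fast Use the reduced optimisation budget of [fit_sse_ml()] for
#'   every fit (default TRUE); observed and simulated data go through the
#'   identical procedure, which is what the calibration compares.
#' @return Object of class `calibration_result`: `observed_p`, `null_ps`,
#'   `cutoff`, `significant`, `redraws`, `rates`.
#' @export
calibrate_lrt <- function(tree, trait, rates = NULL, root_state = "0",
                          n_rep = 100, percentile = 0.05, f = 1,
                          gains_only = FALSE, seed = NULL, n_starts = 1,
                          fast = TRUE) {
  x <- trait[tree$tip.label]
  if (any(is.na(x))) stop("NA tip states; prune unscored species first")
  if (is.null(rates)) {
    fit <- fit_mk_ml(tree, setNames(as.character(x), names(x)),
                     states = c("0", "1"))
    rates <- fit$er$model$Q
  }
  .validate_generator(rates)
  if (gains_only) {
    rates[2, 1] <- 0
    diag(rates) <- 0; diag(rates) <- -rowSums(rates)
  }
  cons <- c("lambda1==lambda0", "mu1==mu0")
  lrt_p <- function(states) {
    cmp <- fit_sse_ml(tree, setNames(as.character(states), names(states)),
                      "bisse", constraints = cons, f = f,
                      n_starts = n_starts, fast = fast)
    cmp$lrt$p
  }
  root_idx <- if (identical(root_state, "0") || identical(root_state, 0))
    1L else 2L
  .with_seed(seed, {
    observed_p <- lrt_p(x)
    null_ps <- numeric(n_rep)
    redraws <- 0L
    for (i in seq_len(n_rep)) {
      repeat {
        sim <- simulate_mk_trait(tree, rates, root_state = root_idx)
        st <- sim$tip_states - 1L
        if (length(unique(st)) == 2) break
        redraws <- redraws + 1L
        if (redraws > 100 * n_rep)
          stop("could not obtain polymorphic simulated traits")
      }
      null_ps[i] <- lrt_p(st[tree$tip.label])
    }
    cutoff <- sort(null_ps)[max(1L, ceiling(percentile * n_rep))]
    structure(list(observed_p = observed_p, null_ps = null_ps,
                   cutoff = cutoff,
                   significant = observed_p < cutoff,
                   redraws = redraws, rates = rates, n_rep = n_rep,
                   seed = seed),
              class = "calibration_result")
  })
}
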