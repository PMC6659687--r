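# Trait-dependent diversification: BiSSE, MuSSE, the additive two-trait
# main-effects model, ML fitting with constraints/AIC/LRT, and Bayesian
# MCMC under exponential priors with rate 1/(2r).

#' State-dependent diversification parameters
#'
#' @param lambda,mu Per-state speciation and extinction rates (events/Myr,
#'   >= 0), equal length k.
#' @param q Transition rates: a k x k matrix (diagonal ignored), or for
#'   k = 2 a length-2 vector `c(q01, q10)`.
#' @param f Sampling fraction in (0, 1], applied to all states.
#' @return Object of class `sse_params`.
#' @export
sse_params <- function(lambda, mu, q, f = 1) {
  k <- length(lambda)
  stopifnot(length(mu) == k, all(lambda >= 0), all(mu >= 0),
            f > 0, f <= 1)
  if (is.matrix(q)) {
    stopifnot(nrow(q) == k, ncol(q) == k, all(q[row(q) != col(q)] >= 0))
    Q <- q
  } else {
    stopifnot(k == 2, length(q) == 2, all(q >= 0))
    Q <- matrix(c(0, q[2], q[1], 0), 2, 2)
  }
  diag(Q) <- 0
  structure(list(lambda = lambda, mu = mu, Q = Q, f = f, k = k),
            class = "sse_params")
}

#' Sampling fraction from species counts
#'
#' @param n_scored Number of scored species present in the tree.
#' @param n_described Total described species in the clade.
#' @return f = n_scored / n_described.
#' @export
sampling_fraction <- function(n_scored, n_described) {
  if (n_scored <= 0 || n_described <= 0 || n_scored > n_described)
    stop("need 0 < n_scored <= n_described")
  n_scored / n_described
}

.sse_prep <- function(tree, tip_states, states, f, ultra_tol = 1e-6) {
  td <- .tree_prep(tree)
  chk <- check_ultrametric(td$tree, ultra_tol)
  if (!chk$ultrametric)
    stop("tree is not ultrametric (max relative deviation ",
         format(chk$max_deviation, digits = 3), ")")
  x <- tip_states[td$tree$tip.label]
  if (any(is.na(x)))
    stop("NA tip states; prune unscored species before SSE analysis")
  k <- length(states)
  D <- matrix(0, td$ntip, k)
  idx <- match(as.character(x), as.character(states))
  if (any(is.na(idx))) stop("tip states outside the declared state set")
  D[cbind(seq_len(td$ntip), idx)] <- f
  list(td = td, tipD = D, e0 = rep(1 - f, k))
}

.sse_ll <- function(prep, lambda, mu, Q, root, root_prior, cond_surv,
                    rtol, atol) {
  rs <- .root_spec(root, Q = Q, prior = root_prior, k = length(lambda))
  sse_loglik_cpp(prep$td$edge, prep$td$el, prep$tipD, prep$e0,
                 lambda, mu, Q, rs$mode, rs$prior, cond_surv,
                 rtol, atol)$loglik
}

#' BiSSE log-likelihood
#'
#' Binary state speciation and extinction: backward integration of the
#' coupled extinction/data ODEs along each branch (adaptive stepper,
#' tolerances 1e-8), node combination `D = lambda * D_left * D_right` with
#' per-node rescaling, tip conditions `D = f * indicator`,
#' `E(0) = 1 - f`, and a state-weighted root with conditioning on the
#' survival of both root lineages.  The six parameters are the two
#' speciation, two extinction and two transition rates.
#'
#' @param tree Ultrametric `phylo` pruned to scored species.
#' @param tip_states Named 0/1 vector over the tips.
#' @param params [sse_params()] with k = 2, or a named vector
#'   `c(lambda0, lambda1, mu0, mu1, q01, q10)`.
#' @param f Sampling fraction (overridden by `params$f` if given there).
#' @param root Root weighting: `"fitzjohn"` (default; weights
#'   proportional to each state's likelihood of the data), `"uniform"`,
#'   `"stationary"` or `"given"` with `root_prior`.
#' @param root_prior Optional root state probabilities.
#' @param cond_surv Condition on survival of the two root lineages
#'   (default TRUE).
#' @param rtol,atol ODE tolerances.
#' @return Log-likelihood.
#' @export
bisse_loglik <- function(tree, tip_states, params, f = 1,
                         root = "fitzjohn", root_prior = NULL,
                         cond_surv = TRUE, rtol = 1e-8, atol = 1e-8) {
  if (!inherits(params, "sse_params")) {
    p <- params[c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")]
    if (any(is.na(p))) stop("params must name lambda0, lambda1, mu0, mu1, ",
                            "q01, q10")
    params <- sse_params(p[1:2], p[3:4], c(p[5], p[6]), f = f)
  }
  musse_loglik(tree, tip_states, params, states = c("0", "1"),
               root = root, root_prior = root_prior,
               cond_surv = cond_surv, rtol = rtol, atol = atol)
}

#' MuSSE log-likelihood
#'
#' k-state generalisation of [bisse_loglik()]; for k = 4 the free
#' parameter count is 4 speciation + 4 extinction + 12 transition = 20.
#'
#' @inheritParams bisse_loglik
#' @param params An [sse_params()] with k states.
#' @param states State labels matching the tip coding (defaults to the
#'   sorted observed states).
#' @return Log-likelihood.
#' @export
musse_loglik <- function(tree, tip_states, params, states = NULL,
                         root = "fitzjohn", root_prior = NULL,
                         cond_surv = TRUE, rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(params, "sse_params"))
  if (is.null(states))
    states <- sort(unique(as.character(tip_states[!is.na(tip_states)])))
  if (length(states) != params$k)
    stop("state labels do not match parameter dimension")
  prep <- .sse_prep(tree, tip_states, states, params$f)
  .sse_ll(prep, params$lambda, params$mu, params$Q, root, root_prior,
          cond_surv, rtol, atol)
}

# expand additive two-trait main effects to 4 joint states
# joint order: (0,0), (0,1), (1,0), (1,1) over (traitA, traitB)
.multitrait_expand <- function(p) {
  a <- c(0, 0, 1, 1); b <- c(0, 1, 0, 1)
  lambda <- p["lambda0"] + a * p["lambdaA"] + b * p["lambdaB"]
  mu <- p["mu0"] + a * p["muA"] + b * p["muB"]
  if (any(lambda < 0) || any(mu < 0)) return(NULL)
  Q <- matrix(0, 4, 4)
  Q[1, 3] <- Q[2, 4] <- p["qA01"]  # trait A gain
  Q[3, 1] <- Q[4, 2] <- p["qA10"]  # trait A loss
  Q[1, 2] <- Q[3, 4] <- p["qB01"]  # trait B gain
  Q[2, 1] <- Q[4, 3] <- p["qB10"]  # trait B loss
  list(lambda = unname(lambda), mu = unname(mu), Q = Q)
}

.MULTITRAIT_PARS <- c("lambda0", "lambdaA", "lambdaB", "mu0", "muA", "muB",
                      "qA01", "qA10", "qB01", "qB10")

#' Two-trait main-effects SSE log-likelihood
#'
#' Ten-parameter model: additive main effects of two binary traits on
#' speciation and extinction, `lambda(a, b) = lambda0 + a lambdaA +
#' b lambdaB` (and likewise for mu), with an independent 4-rate model of
#' character evolution (gain/loss of each trait; dual transitions zero),
#' expanded to a 4-joint-state MuSSE and evaluated by the same machinery.
#'
#' @inheritParams bisse_loglik
#' @param traitA,traitB Named 0/1 vectors over the tips.
#' @param params Named vector over
#'   `lambda0, lambdaA, lambdaB, mu0, muA, muB, qA01, qA10, qB01, qB10`.
#' @return Log-likelihood.
#' @export
multitrait_sse_loglik <- function(tree, traitA, traitB, params, f = 1,
                                  root = "fitzjohn", root_prior = NULL,
                                  cond_surv = TRUE, rtol = 1e-8,
                                  atol = 1e-8) {
  p <- params[.MULTITRAIT_PARS]
  if (any(is.na(p))) stop("params must name: ",
                          paste(.MULTITRAIT_PARS, collapse = ", "))
  ex <- .multitrait_expand(p)
  if (is.null(ex)) stop("implied per-state rate is negative")
  joint <- encode_joint_states(traitA, traitB)
  tree2 <- prune_to_taxa(tree, names(joint))
  pars <- sse_params(ex$lambda, ex$mu, ex$Q, f = f)
  musse_loglik(tree2, setNames(as.character(joint), names(joint)), pars,
               states = c("1", "2", "3", "4"), root = root,
               root_prior = root_prior, cond_surv = cond_surv,
               rtol = rtol, atol = atol)
}

# ---- internal model description shared by ML and MCMC -------------------

.sse_model_desc <- function(model_spec, tree, states, traitA = NULL,
                            traitB = NULL, f = 1) {
  if (model_spec == "multitrait") {
    joint <- encode_joint_states(traitA, traitB)
    tree2 <- prune_to_taxa(tree, names(joint))
    tip <- setNames(as.character(joint), names(joint))
    lab <- c("1", "2", "3", "4")
    par_names <- .MULTITRAIT_PARS
    par_type <- setNames(c("pos", "real", "real", "pos", "real", "real",
                           "pos", "pos", "pos", "pos"), par_names)
    build <- function(p) .multitrait_expand(p)
    k <- 4
  } else {
    tip <- states  # named tip-state vector
    lab <- sort(unique(as.character(tip[!is.na(tip)])))
    k <- length(lab)
    if (model_spec == "bisse" && k != 2)
      stop("bisse requires exactly 2 observed states")
    qn <- as.vector(outer(lab, lab, function(i, j) paste0("q", i, j)))
    qn <- qn[as.vector(outer(lab, lab, `!=`))]
    par_names <- c(paste0("lambda", lab), paste0("mu", lab), qn)
    par_type <- setNames(rep("pos", length(par_names)), par_names)
    build <- function(p) {
      lambda <- unname(p[paste0("lambda", lab)])
      mu <- unname(p[paste0("mu", lab)])
      Q <- matrix(0, k, k)
      for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
        Q[i, j] <- p[paste0("q", lab[i], lab[j])]
      if (any(lambda < 0) || any(mu < 0) || any(Q < 0)) return(NULL)
      list(lambda = lambda, mu = mu, Q = Q)
    }
    tree2 <- tree
  }
  list(par_names = par_names, par_type = par_type, build = build,
       tree = tree2, tip = tip, states = lab, k = k, f = f)
}

.parse_constraints <- function(par_names, constraints) {
  parent <- setNames(par_names, par_names)
  fixed <- setNames(rep(NA_real_, length(par_names)), par_names)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (con in constraints) {
    parts <- strsplit(gsub(" ", "", con), "==")[[1]]
    if (length(parts) != 2) stop("bad constraint: ", con)
    lhs <- parts[1]; rhs <- parts[2]
    if (!lhs %in% par_names) stop("unknown parameter in constraint: ", lhs)
    num <- suppressWarnings(as.numeric(rhs))
    if (!is.na(num)) {
      fixed[find(lhs)] <- num
    } else {
      if (!rhs %in% par_names) stop("unknown parameter in constraint: ", rhs)
      a <- find(lhs); b <- find(rhs)
      if (a != b) {
        if (!is.na(fixed[a]) && is.na(fixed[b])) fixed[b] <- fixed[a]
        parent[[a]] <- b
      }
    }
  }
  reps <- vapply(par_names, find, character(1))
  rep_fixed <- fixed[reps]
  free <- unique(reps[is.na(rep_fixed)])
  expand <- function(theta) {
    full <- setNames(numeric(length(par_names)), par_names)
    for (nm in par_names) {
      r <- reps[[nm]]
      full[nm] <- if (!is.na(fixed[r])) fixed[r] else theta[[r]]
    }
    full
  }
  list(free = free, expand = expand, n_free = length(free))
}

.sse_start <- function(desc) {
  depth <- max(ape::node.depth.edgelength(desc$tree))
  ntip <- length(desc$tree$tip.label)
  r0 <- max(log(ntip / 2) / depth, 1e-3)
  st <- setNames(numeric(length(desc$par_names)), desc$par_names)
  for (nm in desc$par_names) {
    st[nm] <- if (desc$par_type[nm] == "real") 0
    else if (startsWith(nm, "lambda")) r0 * 1.2
    else if (startsWith(nm, "mu")) r0 * 0.1
    else r0 * 0.1
  }
  st
}

#' Fit a state-dependent diversification model by maximum likelihood
#'
#' Bounded multistart optimisation; when `constraints` are supplied the
#' full and constrained models are both fitted and compared with a
#' likelihood-ratio test (chi-square, df = difference in free parameters)
#' and AIC.
#'
#' @param tree Ultrametric `phylo` object.
#' @param states Named tip-state vector (`bisse`/`musse`), or for
#'   `model_spec = "multitrait"` a list with elements `traitA`, `traitB`.
#' @param model_spec `"bisse"`, `"musse"` or `"multitrait"`.
#' @param constraints Character vector of equality constraints such as
#'   `"lambda1==lambda0"` or `"mu1==0"` defining the constrained model.
#' @param f Sampling fraction.
#' @param root,root_prior,cond_surv Root treatment, see [bisse_loglik()].
#' @param n_starts Optimiser restarts.
#' @param seed Seed for restart jitter.
#' @param rtol,atol ODE tolerances used during the fit.
#' @param fast Reduced optimisation budget (single start, shorter search,
#'   looser ODE tolerance); intended for simulation loops such as
#'   [calibrate_lrt()] where the same procedure is applied to observed and
#'   simulated data alike.
#' @return With no constraints, an object of class `sse_fit` (`par`,
#'   `loglik`, `aic`, `n_free`, `d` = per-state net diversification).
#'   With constraints, a class `sse_ml_comparison` list: `full`,
#'   `constrained`, `lrt` (stat, df, p) and `aic` table.
#' @export
fit_sse_ml <- function(tree, states, model_spec = c("bisse", "musse",
                                                    "multitrait"),
                       constraints = NULL, f = 1, root = "fitzjohn",
                       root_prior = NULL, cond_surv = TRUE, n_starts = 3,
                       seed = 1, rtol = 1e-7, atol = 1e-7, fast = FALSE) {
  if (fast) { n_starts <- 1; rtol <- max(rtol, 1e-6); atol <- max(atol, 1e-6) }
  model_spec <- match.arg(model_spec)
  desc <- if (model_spec == "multitrait")
    .sse_model_desc(model_spec, tree, NULL, states$traitA, states$traitB,
                    f = f)
  else .sse_model_desc(model_spec, tree, states, f = f)
  fit_one <- function(cons) {
    pc <- .parse_constraints(desc$par_names, cons %||% character())
    prep <- .sse_prep(desc$tree, desc$tip, desc$states, f)
    # rates far above ~100 expected events on a mean edge are outside any
    # identifiable regime and only drive the ODEs stiff; box them out so
    # the derivative-free search stays in sane territory
    rate_cap <- 100 / mean(prep$td$el)
    nll <- function(theta_t) {
      theta <- theta_t
      for (i in seq_along(pc$free))
        if (desc$par_type[[pc$free[i]]] == "pos") theta[i] <- exp(theta[i])
      names(theta) <- pc$free
      if (any(abs(theta) > rate_cap)) return(1e10)
      full <- pc$expand(theta)
      m <- desc$build(full)
      if (is.null(m)) return(1e10)
      if (any(m$lambda > rate_cap) || any(m$mu > rate_cap) ||
          any(m$Q > rate_cap))
        return(1e10)
      ll <- .sse_ll(prep, m$lambda, m$mu, m$Q, root, root_prior,
                    cond_surv, rtol, atol)
      if (!is.finite(ll)) 1e10 else -ll
    }
    st0 <- .sse_start(desc)
    best <- NULL
    starts <- .with_seed(seed, lapply(seq_len(n_starts), function(i) {
      s <- st0
      if (i > 1) {
        pos <- desc$par_type[names(s)] == "pos"
        s[pos] <- s[pos] * exp(runif(sum(pos), -1, 1))
        s[!pos] <- s[!pos] + rnorm(sum(!pos), 0, 0.3 * max(s))
      }
      s
    }))
    for (s in starts) {
      th0 <- vapply(pc$free, function(nm)
        if (desc$par_type[[nm]] == "pos") log(max(s[[nm]], 1e-8))
        else s[[nm]], numeric(1))
      # Nelder-Mead with one restart from the incumbent; derivative-free
      # search avoids finite-difference excursions into slow ODE regimes
      o <- tryCatch({
        if (length(th0) == 1) {
          oo <- stats::optimize(function(z) nll(setNames(z, names(th0))),
                                c(log(1e-8), log(1e3)))
          list(par = setNames(oo$minimum, names(th0)),
               value = oo$objective, convergence = 0L)
        } else if (fast) {
          stats::optim(th0, nll, method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-8))
        } else {
          o1 <- stats::optim(th0, nll, method = "Nelder-Mead",
                             control = list(maxit = 1500, reltol = 1e-9))
          stats::optim(o1$par, nll, method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-9))
        }
      }, error = function(e) NULL)
      if (is.null(o) && length(th0) > 1)
        o <- tryCatch(
          stats::optim(th0, nll, method = "L-BFGS-B",
                       lower = ifelse(desc$par_type[pc$free] == "pos",
                                      log(1e-8), -1e3),
                       upper = ifelse(desc$par_type[pc$free] == "pos",
                                      log(1e3), 1e3),
                       control = list(maxit = 500)),
          error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("SSE optimisation failed in all restarts")
    theta <- best$par
    for (i in seq_along(pc$free))
      if (desc$par_type[[pc$free[i]]] == "pos") theta[i] <- exp(theta[i])
    names(theta) <- pc$free
    par <- pc$expand(theta)
    ll <- -best$value
    m <- desc$build(par)
    structure(list(par = par, loglik = ll, n_free = pc$n_free,
                   aic = 2 * pc$n_free - 2 * ll,
                   d = if (!is.null(m))
                     setNames(m$lambda - m$mu, desc$states) else NULL,
                   model_spec = model_spec, states = desc$states, f = f,
                   constraints = cons, convergence = best$convergence,
                   tree = desc$tree, tip = desc$tip, root = root,
                   cond_surv = cond_surv),
              class = "sse_fit")
  }
  if (is.null(constraints) || !length(constraints)) return(fit_one(NULL))
  full <- fit_one(NULL)
  constrained <- fit_one(constraints)
  stat <- 2 * (full$loglik - constrained$loglik)
  df <- full$n_free - constrained$n_free
  p <- stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE)
  aic <- data.frame(model = c("full", "constrained"),
                    df = c(full$n_free, constrained$n_free),
                    loglik = c(full$loglik, constrained$loglik),
                    aic = c(full$aic, constrained$aic))
  structure(list(full = full, constrained = constrained,
                 lrt = list(stat = stat, df = df, p = p), aic = aic),
            class = "sse_ml_comparison")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# univariate slice sampler (stepping out + shrinkage)
.slice1 <- function(x0, logf, w, lower = -Inf, upper = Inf, m = 50) {
  y <- logf(x0) + log(runif(1))
  L <- x0 - runif(1) * w
  R <- L + w
  j <- floor(runif(1) * m); kk <- m - 1 - j
  while (j > 0 && L > lower && logf(L) > y) { L <- L - w; j <- j - 1 }
  while (kk > 0 && R < upper && logf(R) > y) { R <- R + w; kk <- kk - 1 }
  L <- max(L, lower); R <- min(R, upper)
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

#' Bayesian MCMC for state-dependent diversification
#'
#' Univariate slice-sampling updates of every free parameter under
#' independent exponential priors with rate 1/(2r) (mean 2r), r being the
#' character-independent diversification rate; signed main effects in the
#' multitrait model receive a Laplace(0, 2r) prior.  The first 10\% of
#' generations are discarded as burn-in.  Starting values default to the
#' ML estimates.
#'
#' @inheritParams fit_sse_ml
#' @param r Character-independent net diversification rate (> 0) used to
#'   set the prior rate 1/(2r).
#' @param n_gen Number of MCMC generations (default 10000).
#' @param start Optional named start vector; defaults to the ML fit (or
#'   prior means when `use_lik = FALSE`).
#' @param use_lik Set `FALSE` to sample the prior (validation).
#' @param seed Optional RNG seed.
#' @return Object of class `sse_posterior`: `samples` (data frame),
#'   `summary` (mean, median, 2.5\% and 97.5\% quantiles per parameter and
#'   per-state net diversification), `burnin`, `config`.
#' @export
sse_mcmc <- function(tree, states, model_spec = c("bisse", "musse",
                                                  "multitrait"),
                     r, n_gen = 10000, seed = NULL, f = 1,
                     start = NULL, use_lik = TRUE, root = "fitzjohn",
                     root_prior = NULL, cond_surv = TRUE,
                     rtol = 1e-7, atol = 1e-7) {
  model_spec <- match.arg(model_spec)
  if (r <= 0) stop("r must be > 0")
  desc <- if (model_spec == "multitrait")
    .sse_model_desc(model_spec, tree, NULL, states$traitA, states$traitB,
                    f = f)
  else .sse_model_desc(model_spec, tree, states, f = f)
  prep <- .sse_prep(desc$tree, desc$tip, desc$states, f)
  prior_mean <- 2 * r
  lprior <- function(nm, x) {
    if (desc$par_type[[nm]] == "pos")
      stats::dexp(x, rate = 1 / prior_mean, log = TRUE)
    else -abs(x) / prior_mean - log(2 * prior_mean)
  }
  loglik <- function(p) {
    m <- desc$build(p)
    if (is.null(m)) return(-Inf)
    .sse_ll(prep, m$lambda, m$mu, m$Q, root, root_prior, cond_surv,
            rtol, atol)
  }
  if (is.null(start)) {
    if (use_lik) {
      fit <- fit_sse_ml(tree, states, model_spec, f = f, root = root,
                        root_prior = root_prior, cond_surv = cond_surv,
                        n_starts = 2, rtol = rtol, atol = atol)
      start <- fit$par
    } else {
      start <- setNames(rep(prior_mean, length(desc$par_names)),
                        desc$par_names)
      start[desc$par_type == "real"] <- 0
    }
  }
  .with_seed(seed, {
    p <- start[desc$par_names]
    ll <- if (use_lik) loglik(p) else 0
    ns <- length(desc$par_names)
    out <- matrix(NA_real_, n_gen, ns + 1)
    colnames(out) <- c(desc$par_names, "loglik")
    for (g in seq_len(n_gen)) {
      for (nm in desc$par_names) {
        lower <- if (desc$par_type[[nm]] == "pos") 0 else -1e3
        w <- max(prior_mean / 2, abs(p[[nm]]) / 2, 1e-3)
        logf <- function(x) {
          pp <- p; pp[[nm]] <- x
          lp <- lprior(nm, x)
          if (!is.finite(lp)) return(-Inf)
          if (!use_lik) return(lp)
          l2 <- loglik(pp)
          if (!is.finite(l2)) return(-Inf)
          lp + l2
        }
        p[[nm]] <- .slice1(p[[nm]], logf, w, lower = lower, upper = 1e3)
      }
      if (use_lik) ll <- loglik(p)
      out[g, ] <- c(p, if (use_lik) ll else NA_real_)
    }
    burn <- floor(n_gen * 0.10)
    kept <- as.data.frame(out[(burn + 1):n_gen, , drop = FALSE])
    summ <- do.call(rbind, lapply(desc$par_names, function(nm) {
      v <- kept[[nm]]
      data.frame(param = nm, mean = mean(v), median = median(v),
                 lower95 = unname(quantile(v, 0.025)),
                 upper95 = unname(quantile(v, 0.975)))
    }))
    structure(list(samples = kept, summary = summ, burnin = burn,
                   model_spec = model_spec, states = desc$states,
                   par_names = desc$par_names, build = desc$build,
                   config = list(r = r, n_gen = n_gen, seed = seed, f = f)),
              class = "sse_posterior")
  })
}

#' Net diversification rates
#'
#' Per-state net diversification d = lambda - mu, at the ML estimate for a
#' fit or per posterior sample (with 95\% credibility intervals and both
#' mean and median point summaries) for an MCMC run.
#'
#' @param x An `sse_fit` or `sse_posterior`.
#' @return Named vector (fit) or data frame (posterior).
#' @export
net_diversification <- function(x) UseMethod("net_diversification")

#' @export
net_diversification.sse_fit <- function(x) x$d

#' @export
net_diversification.sse_posterior <- function(x) {
  S <- x$samples
  dmat <- t(apply(S[, x$par_names, drop = FALSE], 1, function(p) {
    m <- x$build(setNames(as.numeric(p), x$par_names))
    if (is.null(m)) rep(NA_real_, length(x$states)) else m$lambda - m$mu
  }))
  colnames(dmat) <- x$states
  do.call(rbind, lapply(x$states, function(st) {
    v <- dmat[, st]
    data.frame(state = st, mean = mean(v, na.rm = TRUE),
               median = median(v, na.rm = TRUE),
               lower95 = unname(quantile(v, 0.025, na.rm = TRUE)),
               upper95 = unname(quantile(v, 0.975, na.rm = TRUE)))
  }))
}
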