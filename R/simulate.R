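# Forward simulators with known ground truth: birth-death and
# state-dependent trees, discrete trait histories on fixed trees, and
# brood-level embryo-mass data.

# Gillespie forward simulation of a state-dependent birth-death process
# from two crown lineages.  Returns the lineage table and stop time, or
# NULL on total extinction / failure to reach the requested tip count.
.sim_forward <- function(lambda, mu, Q, root_state, stop_n = NULL,
                         stop_age = NULL, max_events = 1e6) {
  k <- length(lambda)
  qq <- Q
  if (k > 1) diag(qq) <- 0
  qout <- rowSums(qq)
  # lineage fields grown in lists
  parent <- c(0L, 0L); t_birth <- c(0, 0)
  state <- c(root_state, root_state)
  alive <- c(TRUE, TRUE)
  t_end <- c(NA_real_, NA_real_)
  fate <- c("", "")          # "split", "extinct", "extant"
  hist <- list(list(t = 0, s = root_state), list(t = 0, s = root_state))
  children <- list(integer(0), integer(0))
  t_now <- 0
  for (ev in seq_len(max_events)) {
    idx <- which(alive)
    n_ext <- length(idx)
    if (n_ext == 0) return(NULL)
    if (!is.null(stop_n) && n_ext >= stop_n) {
      # present falls uniformly between this moment and the next event
      rates_i <- lambda[state[idx]] + mu[state[idx]] +
        (if (k > 1) qout[state[idx]] else 0)
      tot <- sum(rates_i)
      gap <- if (tot > 0) rexp(1, tot) else 1
      t_now <- t_now + runif(1) * gap
      break
    }
    rates_i <- lambda[state[idx]] + mu[state[idx]] +
      (if (k > 1) qout[state[idx]] else 0)
    tot <- sum(rates_i)
    if (tot <= 0) {
      if (is.null(stop_age)) return(NULL)
      t_now <- stop_age
      break
    }
    dt <- rexp(1, tot)
    if (!is.null(stop_age) && t_now + dt >= stop_age) {
      t_now <- stop_age
      break
    }
    t_now <- t_now + dt
    li <- idx[sample.int(n_ext, 1, prob = rates_i)]
    s <- state[li]
    u <- runif(1) * (lambda[s] + mu[s] + (if (k > 1) qout[s] else 0))
    if (u < lambda[s]) {
      # speciation: lineage li splits into two new lineages
      alive[li] <- FALSE; t_end[li] <- t_now; fate[li] <- "split"
      for (cc in 1:2) {
        parent <- c(parent, li); t_birth <- c(t_birth, t_now)
        state <- c(state, s); alive <- c(alive, TRUE)
        t_end <- c(t_end, NA_real_); fate <- c(fate, "")
        hist[[length(hist) + 1]] <- list(t = t_now, s = s)
        children[[length(children) + 1]] <- integer(0)
        children[[li]] <- c(children[[li]], length(parent))
      }
    } else if (u < lambda[s] + mu[s]) {
      alive[li] <- FALSE; t_end[li] <- t_now; fate[li] <- "extinct"
    } else {
      # character transition
      w <- qq[s, ]; w[s] <- 0
      s2 <- sample.int(k, 1, prob = w)
      state[li] <- s2
      hist[[li]]$t <- c(hist[[li]]$t, t_now)
      hist[[li]]$s <- c(hist[[li]]$s, s2)
    }
  }
  idx <- which(alive)
  if (length(idx) < 2) return(NULL)
  t_end[idx] <- t_now; fate[idx] <- "extant"
  list(parent = parent, t_birth = t_birth, t_end = t_end, fate = fate,
       state = state, hist = hist, children = children, present = t_now)
}

# assemble a Newick string from the lineage table (full tree incl. extinct)
.lineage_newick <- function(sim) {
  build <- function(i) {
    len <- sim$t_end[i] - sim$t_birth[i]
    if (sim$fate[i] == "split") {
      ch <- sim$children[[i]]
      paste0("(", build(ch[1]), ",", build(ch[2]), "):",
             format(len, digits = 12))
    } else {
      paste0("t", i, ":", format(len, digits = 12))
    }
  }
  paste0("(", build(1), ",", build(2), ");")
}

.sim_build <- function(sim, prune_extinct = TRUE) {
  txt <- .lineage_newick(sim)
  tree <- ape::read.tree(text = txt)
  tip_lineage <- as.integer(sub("^t", "", tree$tip.label))
  if (prune_extinct) {
    dead <- tree$tip.label[sim$fate[tip_lineage] == "extinct"]
    if (length(dead) >= length(tree$tip.label) - 1) return(NULL)
    if (length(dead)) tree <- ape::drop.tip(tree, dead)
  }
  tree$root.edge <- NULL
  tree
}

#' Simulate a constant-rate birth-death tree
#'
#' Forward Gillespie simulation from two crown lineages; extinct lineages
#' are pruned so the returned tree is ultrametric.  Stopping is either at
#' a fixed crown `age` or at the moment the extant lineage count first
#' reaches `n_tips` (the present is then placed uniformly between that
#' birth and the next event).  Total extinction triggers a retry with a
#' logged count.
#'
#' @param lambda,mu Speciation and extinction rates (lambda > mu >= 0).
#' @param stop List with exactly one of `n_tips` or `age`.
#' @param seed Optional RNG seed (same seed, same tree).
#' @return List of class `simulation_record`: `tree` (`phylo`),
#'   `tip_states` (`NULL` here), `record` (generator name, parameters,
#'   seed, retries, lineage table).
#' @export
simulate_bd_tree <- function(lambda, mu = 0, stop = list(n_tips = 50),
                             seed = NULL) {
  stopifnot(lambda > mu, mu >= 0)
  params <- sse_params(lambda, mu, matrix(0, 1, 1))
  simulate_bisse_tree(params, stop = stop, root_state = 1, seed = seed,
                      generator = "bd_tree")
}

#' Simulate a state-dependent (BiSSE/MuSSE-type) tree
#'
#' Forward simulation with state-dependent birth and death and character
#' transitions; the reconstructed (extinct-pruned) tree is returned with
#' the tip states at the present.
#'
#' @param params An [sse_params()] (the sampling fraction is ignored:
#'   simulation is complete).
#' @param stop List with one of `n_tips` (extant count) or `age`.
#' @param root_state Starting state of the two crown lineages (1-based
#'   index into the state set).
#' @param seed Optional RNG seed.
#' @param max_retries Retries on total extinction before giving up.
#' @param generator Name recorded in the provenance record.
#' @return List of class `simulation_record` with `tree`, `tip_states`
#'   (named integer vector of 1-based states; relabel as needed) and
#'   `record`.
#' @export
simulate_bisse_tree <- function(params, stop = list(n_tips = 50),
                                root_state = 1, seed = NULL,
                                max_retries = 1000,
                                generator = "bisse_tree") {
  stopifnot(inherits(params, "sse_params"))
  stop_n <- stop$n_tips; stop_age <- stop$age
  if (is.null(stop_n) && is.null(stop_age))
    stop("stop must name n_tips or age")
  .with_seed(seed, {
    retries <- 0L
    repeat {
      sim <- .sim_forward(params$lambda, params$mu, params$Q, root_state,
                          stop_n = stop_n, stop_age = stop_age)
      tree <- if (is.null(sim)) NULL else .sim_build(sim)
      if (!is.null(tree) &&
          (is.null(stop_n) || length(tree$tip.label) == stop_n)) break
      retries <- retries + 1L
      if (retries > max_retries)
        stop("simulation failed after ", max_retries, " retries")
    }
    tip_lineage <- as.integer(sub("^t", "", tree$tip.label))
    tip_states <- setNames(sim$state[tip_lineage], tree$tip.label)
    structure(list(
      tree = tree, tip_states = tip_states,
      record = list(generator = generator, seed = seed,
                    params = list(lambda = params$lambda, mu = params$mu,
                                  Q = params$Q, root_state = root_state,
                                  stop = stop),
                    retries = retries, present = sim$present,
                    lineages = sim[c("parent", "t_birth", "t_end",
                                     "fate", "state")])),
      class = "simulation_record")
  })
}

#' Simulate a discrete character on a fixed tree
#'
#' Continuous-time Markov simulation from the root state down every edge;
#' change times are recorded per edge.
#'
#' @param tree A `phylo` object.
#' @param Q Generator matrix.
#' @param root_state 1-based root state index.
#' @param seed Optional RNG seed.
#' @return List of class `mk_history`: `tip_states` (named, 1-based
#'   indices), `n_changes`, `edge_history` (per postorder edge: change
#'   times and states), `node_states`.
#' @export
simulate_mk_trait <- function(tree, Q, root_state = 1, seed = NULL) {
  .validate_generator(Q)
  k <- nrow(Q)
  td <- .tree_prep(tree)
  edge <- td$edge; el <- td$el
  nnode <- max(edge)
  root <- edge[nrow(edge), 1]
  .with_seed(seed, {
    st <- integer(nnode)
    st[root] <- root_state
    n_changes <- 0L
    edge_history <- vector("list", nrow(edge))
    for (e in rev(seq_len(nrow(edge)))) {  # preorder
      s <- st[edge[e, 1]]
      tt <- 0; times <- 0; states <- s
      repeat {
        rate <- -Q[s, s]
        if (rate <= 0) break
        w <- rexp(1, rate)
        if (tt + w > el[e]) break
        tt <- tt + w
        p <- Q[s, ]; p[s] <- 0
        s <- sample.int(k, 1, prob = p)
        times <- c(times, tt); states <- c(states, s)
        n_changes <- n_changes + 1L
      }
      st[edge[e, 2]] <- s
      edge_history[[e]] <- list(times = times, states = states)
    }
    tips <- seq_len(td$ntip)
    structure(list(tip_states = setNames(st[tips], td$tree$tip.label),
                   node_states = st, n_changes = n_changes,
                   edge_history = edge_history, edge = edge,
                   seed = seed),
              class = "mk_history")
  })
}

#' Simulate two binary traits under a dependent joint model
#'
#' 4-state simulation over joint states 1 = (0,0) ... 4 = (1,1); marginal
#' per-trait tip states are returned alongside the joint states.
#'
#' @param tree A `phylo` object.
#' @param rates Dependent-model rate vector (see [dependent_loglik()]).
#' @param root_joint_state Root joint state (1-4).
#' @param seed Optional RNG seed.
#' @return List: `joint` (named 1-4), `trait1`, `trait2` (named 0/1),
#'   `history` (the underlying `mk_history`).
#' @export
simulate_dependent_traits <- function(tree, rates, root_joint_state = 1,
                                      seed = NULL) {
  stopifnot(length(rates) == 8)
  Q <- .q_dependent(rates)
  h <- simulate_mk_trait(tree, Q, root_state = root_joint_state,
                         seed = seed)
  joint <- h$tip_states
  list(joint = joint,
       trait1 = setNames(as.integer(joint >= 3), names(joint)),
       trait2 = setNames(as.integer(joint %in% c(2, 4)), names(joint)),
       history = h)
}

#' Simulate brood-level embryo-mass observations
#'
#' Developmental stages are uniform over a span centred on the staging
#' scale midpoint, and `ln(dry mass) = ln(egg_mass) +
#' (ln(true_mi)/stage_span) * stage + N(0, noise_sd)`, so a noiseless
#' regression recovers the generating slope exactly and the implied MI is
#' `true_mi`.
#'
#' @param true_mi Generating matrotrophy index (> 0).
#' @param n_broods Number of broods (>= 3).
#' @param stage_range Width of the sampled stage interval (<= stage_span).
#' @param noise_sd SD of ln-mass noise.
#' @param egg_mass Egg dry mass at fertilization (mg).
#' @param stage_span Full staging scale (default 50).
#' @param species,population Labels for the output table.
#' @param seed Optional RNG seed.
#' @return Data frame (species, population, brood_id, stage, dry_mass).
#' @export
simulate_brood_data <- function(true_mi, n_broods = 12, stage_range = 40,
                                noise_sd = 0.15, egg_mass = 1,
                                stage_span = 50, species = "sim_sp",
                                population = "pop1", seed = NULL) {
  stopifnot(true_mi > 0, n_broods >= 3, stage_range <= stage_span)
  .with_seed(seed, {
    lo <- (stage_span - stage_range) / 2
    stage <- runif(n_broods, lo, lo + stage_range)
    slope <- log(true_mi) / stage_span
    lnm <- log(egg_mass) + slope * stage + rnorm(n_broods, 0, noise_sd)
    data.frame(species = species, population = population,
               brood_id = seq_len(n_broods), stage = stage,
               dry_mass = exp(lnm), stringsAsFactors = FALSE)
  })
}
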