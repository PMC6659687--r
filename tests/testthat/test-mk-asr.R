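test_that("pruning likelihood matches the enumeration oracle", {
  set.seed(31)
  # random trees up to 6 tips, 2- and 4-state generators
  for (rep in 1:30) {
    n <- sample(3:6, 1)
    tr <- rand_tree(n)
    k <- sample(c(2, 4), 1)
    Q <- matrix(runif(k * k, 0.05, 1.5), k, k)
    diag(Q) <- 0; diag(Q) <- -rowSums(Q)
    x <- setNames(sample.int(k, n, replace = TRUE), tr$tip.label)
    states <- as.character(seq_len(k) - 1)
    m <- mk_model(states, Q = Q)
    ll <- mk_loglik(tr, setNames(states[x], names(x)), m)
    expect_equal(ll, enum_mk_loglik(tr, x, Q, rep(1 / k, k)),
                 tolerance = 1e-8)
  }
})

test_that("degenerate inputs give the expected frozen values", {
  f <- tempfile(); writeLines("(A:1,B:1);", f)
  tr <- read_tree(f)
  m0 <- mk_model(c("0", "1"), rate = 0)
  expect_equal(mk_loglik(tr, c(A = "0", B = "0"), m0), log(0.5))
  # zero-length star with conflicting tips is impossible data
  f2 <- tempfile(); writeLines("(A:0,B:0);", f2)
  tr0 <- read_tree(f2)
  expect_identical(mk_loglik(tr0, c(A = "0", B = "1"),
                             mk_model(c("0", "1"), rate = 0.5)), -Inf)
  # unknown state label errors
  expect_error(mk_loglik(tr, c(A = "2", B = "0"), m0), "not among")
  # missing tips are ambiguous: all-NA data carry no information
  expect_equal(mk_loglik(tr, c(A = NA, B = NA),
                         mk_model(c("0", "1"), rate = 0.7)), 0)
})

test_that("ML fitting selects sensible models and matches a grid search", {
  set.seed(32)
  sim <- simulate_bd_tree(0.3, 0.05, stop = list(n_tips = 80), seed = 32)
  h <- simulate_mk_trait(sim$tree, oracle_q_er(0.5, 2), 1, seed = 33)
  xs <- setNames(as.character(h$tip_states - 1), names(h$tip_states))
  fit <- fit_mk_ml(sim$tree, xs)
  # ARD nests ER
  expect_gte(fit$ard$loglik, fit$er$loglik - 1e-6)
  # 1-D grid search over the ER rate agrees with the optimiser
  grid <- exp(seq(log(0.01), log(5), length.out = 400))
  gl <- vapply(grid, function(r)
    mk_loglik(sim$tree, xs, mk_model(c("0", "1"), rate = r)), numeric(1))
  expect_equal(fit$er$rate, grid[which.max(gl)], tolerance = 2e-2)
  expect_gte(fit$er$loglik, max(gl) - 1e-4)
  # monomorphic data: rate unidentifiable
  expect_warning(f0 <- fit_mk_ml(sim$tree,
    setNames(rep("0", 80), sim$tree$tip.label), states = "0"),
    "unidentifiable")
  expect_equal(f0$er$rate, 0)
})

test_that("ER data recover the ER model by AIC in most replicates", {
  set.seed(34)
  n_rep <- 60
  sim <- simulate_bd_tree(0.3, 0.05, stop = list(n_tips = 150), seed = 35)
  picks <- replicate(n_rep, {
    h <- simulate_mk_trait(sim$tree, oracle_q_er(0.5, 2),
                           sample.int(2, 1))
    xs <- setNames(as.character(h$tip_states - 1), names(h$tip_states))
    if (length(unique(xs)) < 2) NA_character_
    else fit_mk_ml(sim$tree, xs)$best
  })
  expect_gte(mean(picks == "ER", na.rm = TRUE), 0.8)
})

test_that("marginal ancestral states match symmetry and small-tree oracles", {
  f <- tempfile(); writeLines("(A:1,B:1);", f)
  tr2 <- read_tree(f)
  m <- mk_model(c("0", "1"), rate = 0.3)
  rec <- marginal_ancestral_states(tr2, c(A = "0", B = "1"), m)
  expect_equal(unname(rec$prob[3, ]), c(0.5, 0.5))
  # every node sums to one
  expect_equal(rowSums(rec$prob), rep(1, 3))
  # all tips state 0 under ER pulls every node toward 0
  h <- simulate_bd_tree(0.3, 0, stop = list(n_tips = 20), seed = 36)
  rec0 <- marginal_ancestral_states(
    h$tree, setNames(rep("0", 20), h$tree$tip.label), m)
  expect_true(all(rec0$prob[, "0"] > rec0$prob[, "1"]))

  # 3-tip closed form via the enumeration oracle restricted per root state
  f3 <- tempfile(); writeLines("((A:0.6,B:0.6):0.4,C:1);", f3)
  tr3 <- read_tree(f3)
  Q <- matrix(c(-0.5, 0.5, 0.2, -0.2), 2, 2, byrow = TRUE)
  m3 <- mk_model(c("0", "1"), Q = Q)
  x3 <- c(A = "0", B = "1", C = "1")
  rec3 <- marginal_ancestral_states(tr3, x3, m3)
  # root posterior by brute force: P(root = s | data)
  P <- function(t) expm_o(Q * t)
  lik_root <- vapply(1:2, function(rs) {
    tot <- 0
    for (mid in 1:2)
      tot <- tot + P(0.4)[rs, mid] * P(0.6)[mid, 1] * P(0.6)[mid, 2] *
        P(1)[rs, 2]
    tot * 0.5
  }, numeric(1))
  expect_equal(unname(rec3$prob[4, ]), lik_root / sum(lik_root),
               tolerance = 1e-10)
})

test_that("Fitch parsimony equals the brute-force minimum", {
  set.seed(37)
  sim <- simulate_bd_tree(0.3, 0, stop = list(n_tips = 8), seed = 37)
  same <- setNames(rep(1L, 8), sim$tree$tip.label)
  expect_equal(fitch_parsimony(sim$tree, same, states = c(1, 2))$count, 0)
  one_dev <- same; one_dev[3] <- 2L
  expect_equal(fitch_parsimony(sim$tree, one_dev, states = c(1, 2))$count, 1)
  for (rep in 1:20) {
    n <- sample(4:6, 1)
    tr <- rand_tree(n)
    k <- sample(2:3, 1)
    x <- setNames(sample.int(k, n, replace = TRUE), tr$tip.label)
    fp <- fitch_parsimony(tr, x, states = seq_len(k))
    expect_equal(fp$count, enum_parsimony(tr, x, k))
  }
})

test_that("origin counting reads gains and losses off reconstructions", {
  # hand-built: two independent gains among 5 tips
  f <- tempfile()
  writeLines("(((A:1,B:1):1,(C:1,D:1):1):1,E:3);", f)
  tr <- read_tree(f)
  x <- c(A = "1", B = "0", C = "1", D = "0", E = "0")
  prob <- matrix(0, 9, 2, dimnames = list(NULL, c("0", "1")))
  prob[, 1] <- 1  # all internal nodes reconstructed as absent
  prob[1:5, ] <- 0
  prob[cbind(1:5, match(x, c("0", "1")))] <- 1
  rec <- structure(list(prob = prob, tree = ape::reorder.phylo(tr, "postorder"),
                        tip_states = x),
                   class = "ancestral_reconstruction")
  oc <- count_origins(rec)
  expect_equal(unname(oc), c(2, 0))
  # constant reconstruction: nothing happens
  x0 <- setNames(rep("0", 5), names(x))
  prob0 <- prob; prob0[1:5, ] <- rep(c(1, 0), each = 5)
  rec0 <- structure(list(prob = prob0, tree = rec$tree, tip_states = x0),
                    class = "ancestral_reconstruction")
  expect_equal(unname(count_origins(rec0)), c(0, 0))
})
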