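test_that("joint state encoding enumerates and excludes correctly", {
  t1 <- c(a = 0, b = 0, c = 1, d = 1, e = 1)
  t2 <- c(a = 0, b = 1, c = 0, d = 1, e = NA)
  expect_message(j <- encode_joint_states(t1, t2), "excluded")
  expect_equal(as.integer(j), c(1L, 2L, 3L, 4L))
  expect_setequal(names(j), c("a", "b", "c", "d"))
  expect_error(encode_joint_states(c(a = 2), c(a = 0)), "0/1")
})

test_that("dependent and independent likelihoods agree with oracles", {
  set.seed(51)
  sim <- simulate_bd_tree(0.3, 0.05, stop = list(n_tips = 25), seed = 51)
  tr <- sim$tree
  t1 <- setNames(rbinom(25, 1, 0.5), tr$tip.label)
  t2 <- setNames(rbinom(25, 1, 0.5), tr$tip.label)
  joint <- encode_joint_states(t1, t2)

  # independent embedding equals the product of two 2-state prunings
  r4 <- c(0.3, 0.2, 0.4, 0.1)
  li <- independent_loglik(tr, joint, r4)
  m1 <- mk_model(c("0", "1"),
                 Q = matrix(c(-r4[1], r4[1], r4[2], -r4[2]), 2, byrow = TRUE))
  m2 <- mk_model(c("0", "1"),
                 Q = matrix(c(-r4[3], r4[3], r4[4], -r4[4]), 2, byrow = TRUE))
  lp <- mk_loglik(tr, setNames(as.character(t1), names(t1)), m1) +
    mk_loglik(tr, setNames(as.character(t2), names(t2)), m2)
  expect_equal(li, lp, tolerance = 1e-10)

  # dependent model with embedded rates reproduces the independent fit
  r8 <- c(r4[3], r4[1], r4[4], r4[1], r4[2], r4[3], r4[2], r4[4])
  expect_equal(dependent_loglik(tr, joint, r8), li, tolerance = 1e-10)

  # trait 2 constant: lnL decomposes into the two marginal chains
  t2c <- setNames(rep(0, 25), tr$tip.label)
  jc <- encode_joint_states(t1, t2c)
  lic <- independent_loglik(tr, jc, r4)
  lpc <- mk_loglik(tr, setNames(as.character(t1), names(t1)), m1) +
    mk_loglik(tr, setNames(as.character(t2c), names(t2c)), m2)
  expect_equal(lic, lpc, tolerance = 1e-10)

  # 3-tip enumeration oracle for the dependent model
  set.seed(52)
  for (rep in 1:15) {
    tr3 <- rand_tree(3)
    rr <- runif(8, 0.05, 1)
    j3 <- setNames(sample.int(4, 3, replace = TRUE), tr3$tip.label)
    expect_equal(dependent_loglik(tr3, j3, rr),
                 enum_mk_loglik(tr3, j3, oracle_q_dep(rr), rep(0.25, 4)),
                 tolerance = 1e-10)
  }

  # all-zero rates with every species in one state
  j1 <- setNames(rep(1L, 25), tr$tip.label)
  expect_equal(dependent_loglik(tr, j1, rep(0, 8)), log(1 / 4))
})

test_that("reversible jump recovers its prior when the likelihood is off", {
  set.seed(53)
  sim <- simulate_bd_tree(0.3, 0.05, stop = list(n_tips = 20), seed = 53)
  joint <- setNames(sample.int(4, 20, replace = TRUE), sim$tree$tip.label)
  post <- rjmcmc_sample(sim$tree, joint, "dependent", iterations = 60000,
                        burnin = 5000, thin = 20, n_chains = 1, seed = 54,
                        use_lik = FALSE)
  v <- unlist(post$samples[post$rate_names])
  # hyperprior-marginal mean of an active rate: E[m] with m ~ U(0, 20) = 10
  pos <- v[v > 0]
  se <- sd(pos) / sqrt(viviphy:::.ess(pos))
  expect_lt(abs(mean(pos) - 10), 3 * se)
  # zero bin occupancy matches its 0.5 prior
  expect_lt(abs(mean(v == 0) - 0.5), 0.03)
  # hyperprior mean itself is U(0, 20)
  expect_lt(abs(mean(post$samples$hyper_mean) - 10), 0.5)
})

test_that("posterior means match quadrature on a small tree", {
  f <- tempfile(); writeLines("((A:1,B:1):0.6,C:1.6);", f)
  tr3 <- read_tree(f)
  j3 <- encode_joint_states(c(A = 0, B = 1, C = 1), c(A = 0, B = 0, C = 0))
  post <- rjmcmc_sample(tr3, j3, "independent", iterations = 2e5,
                        burnin = 2e4, thin = 20, n_chains = 1, seed = 55,
                        rj = FALSE, hyper = FALSE, prior_mean = 1)
  # the joint chain factorises, so the (alpha1, beta1) posterior is exactly
  # the 2-d integral of the trait-1 pruning against its Exp(1) priors
  lik1 <- function(a, b) {
    m <- mk_model(c("0", "1"),
                  Q = matrix(c(-a, a, b, -b), 2, byrow = TRUE))
    exp(mk_loglik(tr3, c(A = "0", B = "1", C = "1"), m))
  }
  num <- stats::integrate(function(av) vapply(av, function(a) {
    stats::integrate(function(bv) vapply(bv, function(b)
      a * lik1(a, b) * dexp(a) * dexp(b), numeric(1)), 0, 30)$value
  }, numeric(1)), 0, 30)$value
  den <- stats::integrate(function(av) vapply(av, function(a) {
    stats::integrate(function(bv) vapply(bv, function(b)
      lik1(a, b) * dexp(a) * dexp(b), numeric(1)), 0, 30)$value
  }, numeric(1)), 0, 30)$value
  target <- num / den
  a1 <- post$samples$alpha1
  se <- sd(a1) / sqrt(viviphy:::.ess(a1))
  expect_lt(abs(mean(a1) - target), 3 * se)
})

test_that("replicate chains agree on simulated data", {
  set.seed(56)
  sim <- simulate_bd_tree(0.3, 0.05, stop = list(n_tips = 40), seed = 56)
  dep <- simulate_dependent_traits(sim$tree,
    c(0.4, 0.1, 0.3, 0.8, 0.2, 0.4, 0.3, 0.2), seed = 57)
  post <- rjmcmc_sample(sim$tree, dep$joint, "dependent",
                        iterations = 3e4, burnin = 3e3, thin = 15,
                        n_chains = 3, seed = 58)
  by_chain <- split(post$samples, post$samples$chain)
  for (rn in post$rate_names) {
    ms <- vapply(by_chain, function(s) mean(s[[rn]]), numeric(1))
    ses <- vapply(by_chain, function(s)
      sd(s[[rn]]) / sqrt(viviphy:::.ess(s[[rn]])), numeric(1))
    for (i in 2:3)
      expect_lt(abs(ms[i] - ms[1]),
                4 * sqrt(ses[i]^2 + ses[1]^2) + 0.05 * max(ms))
  }
})

test_that("stepping stone is exact on flat likelihoods and near quadrature", {
  f <- tempfile(); writeLines("((A:1,B:1):0.6,C:1.6);", f)
  tr3 <- read_tree(f)
  # fully ambiguous data: L = 1, so log marginal likelihood = 0 exactly
  jna <- setNames(rep(NA_integer_, 3), tr3$tip.label)
  ss0 <- stepping_stone_ml(tr3, jna, "independent", n_stones = 10,
                           iters_per_stone = 200, seed = 59)
  expect_equal(ss0$log_ml, 0, tolerance = 1e-12)

  j3 <- encode_joint_states(c(A = 0, B = 1, C = 1), c(A = 0, B = 0, C = 0))
  ss <- stepping_stone_ml(tr3, j3, "independent", n_stones = 40,
                          iters_per_stone = 1500, seed = 60, prior_mean = 1)
  # quadrature: the likelihood factorises into two 2-d integrals
  quad2 <- function(dat) {
    lik <- function(a, b) {
      m <- mk_model(c("0", "1"),
                    Q = matrix(c(-a, a, b, -b), 2, byrow = TRUE))
      exp(mk_loglik(tr3, dat, m))
    }
    stats::integrate(function(av) vapply(av, function(a) {
      stats::integrate(function(bv) vapply(bv, function(b)
        lik(a, b) * dexp(b), numeric(1)), 0, Inf, rel.tol = 1e-9)$value *
        dexp(a)
    }, numeric(1)), 0, Inf, rel.tol = 1e-8)$value
  }
  target <- log(quad2(c(A = "0", B = "1", C = "1"))) +
    log(quad2(c(A = "0", B = "0", C = "0")))
  expect_lt(abs(ss$log_ml - target), 0.1)
  # repeat run within combined Monte-Carlo error
  ss2 <- stepping_stone_ml(tr3, j3, "independent", n_stones = 40,
                           iters_per_stone = 1500, seed = 61,
                           prior_mean = 1)
  expect_lt(abs(ss$log_ml - ss2$log_ml),
            3 * sqrt(ss$se^2 + ss2$se^2) + 0.02)
})

test_that("Bayes factors are labelled by the conventional thresholds", {
  expect_equal(bayes_factor(3, 0)$bf, 6)
  expect_equal(bayes_factor(3, 0)$evidence, "strong")
  expect_equal(bayes_factor(0.5, 0)$evidence, "none")
  expect_equal(bayes_factor(2, 0)$evidence, "positive")
  expect_equal(bayes_factor(5.5, 0)$bf, 11)
  expect_equal(bayes_factor(5.5, 0)$evidence, "very strong")
  eq <- bayes_factor(-1.2, -1.2)
  expect_equal(eq$bf, 0)
  expect_equal(eq$evidence, "none")
  expect_equal(bayes_factor(0, 4, labels = c("dep", "ind"))$winner, "ind")
})

test_that("Z-scores count zero-binned samples and flag support", {
  samples <- data.frame(chain = 1, hyper_mean = 1,
                        matrix(1, 200, 8, dimnames = list(NULL,
                          viviphy:::.DEP_RATES)),
                        loglik = 0)
  samples$q12[1:60] <- 0   # 30% zero
  samples$q13[1:2] <- 0    # 1% zero
  samples$q21[1:160] <- 0  # 80% zero
  post <- structure(list(samples = samples,
                         rate_names = viviphy:::.DEP_RATES,
                         model_family = "dependent"),
                    class = "rj_posterior")
  zt <- z_scores(post)
  expect_equal(zt$z[zt$rate == "q12"], 30)
  expect_equal(zt$z[zt$rate == "q13"], 1)
  expect_true(zt$supported[zt$rate == "q13"])
  expect_false(zt$supported[zt$rate == "q12"])
  expect_false(zt$supported[zt$rate == "q21"])
})
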