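test_that("BiSSE/MuSSE likelihoods match the fine-grid ODE oracle", {
  set.seed(61)
  for (rep in 1:6) {
    n <- sample(5:10, 1)
    tr <- rand_tree(n)
    tr$edge.length <- tr$edge.length * 8  # depths of a few Myr
    k <- if (rep %% 2 == 0) 4 else 2
    lambda <- runif(k, 0.1, 0.5)
    mu <- runif(k, 0.01, 0.08)
    Q <- matrix(runif(k * k, 0.02, 0.1), k, k); diag(Q) <- 0
    x <- sample.int(k, n, replace = TRUE)
    x[1:2] <- c(1L, k)  # both extreme states present
    x <- setNames(x, tr$tip.label)
    f <- sample(c(1, 0.7), 1)
    ours <- musse_loglik(tr, setNames(as.character(x), names(x)),
                         sse_params(lambda, mu, Q, f = f),
                         states = as.character(1:k))
    oracle <- sse_ode_oracle(tr, x, lambda, mu, Q, f = f)
    expect_lt(abs(ours - oracle), 1e-6)
  }
})

test_that("state-homogeneous SSE factorises into birth-death times Mk", {
  set.seed(62)
  sim <- simulate_bd_tree(0.25, 0.05, stop = list(n_tips = 50), seed = 62)
  tr <- sim$tree
  # 2 states
  h <- simulate_mk_trait(tr, oracle_q_er(0.06, 2), 1, seed = 63)
  xs <- setNames(as.character(h$tip_states - 1), names(h$tip_states))
  pars <- c(lambda0 = 0.25, lambda1 = 0.25, mu0 = 0.05, mu1 = 0.05,
            q01 = 0.06, q10 = 0.06)
  lb <- bisse_loglik(tr, xs, pars, root = "fitzjohn")
  mk <- mk_loglik(tr, xs, mk_model(c("0", "1"), rate = 0.06,
                                   root_policy = "fitzjohn"))
  expect_lt(abs(lb - (bd_loglik_closed(tr, 0.25, 0.05) + mk)), 1e-6)
  # 4 states, with sampling fraction
  h4 <- simulate_mk_trait(tr, oracle_q_er(0.03, 4), 2, seed = 64)
  x4 <- setNames(as.character(h4$tip_states), names(h4$tip_states))
  Q4 <- oracle_q_er(0.03, 4); diag(Q4) <- 0
  lm4 <- musse_loglik(tr, x4,
                      sse_params(rep(0.25, 4), rep(0.05, 4), Q4, f = 0.8),
                      states = as.character(1:4), root = "fitzjohn")
  mk4 <- mk_loglik(tr, x4, mk_model(as.character(1:4),
                                    Q = oracle_q_er(0.03, 4),
                                    root_policy = "fitzjohn"))
  expect_lt(abs(lm4 - (bd_loglik_closed(tr, 0.25, 0.05, f = 0.8) + mk4)),
            1e-6)
  # the sampling-fraction switch is active: f = 1 differs from f = 0.5
  expect_gt(abs(bisse_loglik(tr, xs, pars, f = 0.5) -
                bisse_loglik(tr, xs, pars, f = 1)), 1)
})

test_that("the multitrait main-effects model is exactly invertible", {
  set.seed(65)
  sim <- simulate_bd_tree(0.25, 0.05, stop = list(n_tips = 30), seed = 65)
  tr <- sim$tree
  tA <- setNames(rbinom(30, 1, 0.5), tr$tip.label)
  tB <- setNames(rbinom(30, 1, 0.5), tr$tip.label)
  p10 <- c(lambda0 = 0.2, lambdaA = 0.1, lambdaB = -0.05, mu0 = 0.05,
           muA = 0.02, muB = 0.01, qA01 = 0.06, qA10 = 0.03, qB01 = 0.05,
           qB10 = 0.04)
  ex <- viviphy:::.multitrait_expand(p10)
  # forward: additive expansion over joint states (0,0),(0,1),(1,0),(1,1)
  expect_equal(ex$lambda, 0.2 + c(0, 0, 1, 1) * 0.1 + c(0, 1, 0, 1) * -0.05)
  # inverse: main effects recovered from the per-state rates
  expect_equal(unname(c(ex$lambda[1], ex$lambda[3] - ex$lambda[1],
                        ex$lambda[2] - ex$lambda[1])),
               unname(p10[c("lambda0", "lambdaA", "lambdaB")]))
  lmt <- multitrait_sse_loglik(tr, tA, tB, p10)
  jj <- encode_joint_states(tA, tB)
  lms <- musse_loglik(tr, setNames(as.character(jj), names(jj)),
                      sse_params(ex$lambda, ex$mu, ex$Q),
                      states = c("1", "2", "3", "4"))
  expect_equal(lmt, lms, tolerance = 1e-10)
  # zero main effects collapse to a state-homogeneous model
  p0 <- p10; p0[c("lambdaA", "lambdaB", "muA", "muB")] <- 0
  ex0 <- viviphy:::.multitrait_expand(p0)
  expect_equal(ex0$lambda, rep(0.2, 4))
  # implied negative rate is refused
  pneg <- p10; pneg["lambdaB"] <- -0.5
  expect_error(multitrait_sse_loglik(tr, tA, tB, pneg), "negative")
  # parameter counts: 4-state MuSSE exposes 20, multitrait 10
  desc4 <- viviphy:::.sse_model_desc("musse", tr,
    setNames(as.character(jj), names(jj)))
  expect_length(desc4$par_names, 20)
  expect_length(viviphy:::.MULTITRAIT_PARS, 10)
})

test_that("constrained ML fits nest and the LRT machinery is wired", {
  set.seed(66)
  p <- sse_params(c(0.15, 0.15), c(0.03, 0.03), c(0.03, 0.03))
  sim <- simulate_bisse_tree(p, stop = list(n_tips = 60), root_state = 1,
                             seed = 66)
  xs <- setNames(as.character(sim$tip_states - 1), names(sim$tip_states))
  cmp <- fit_sse_ml(sim$tree, xs, "bisse",
                    constraints = c("lambda1==lambda0", "mu1==mu0"),
                    n_starts = 1, fast = TRUE)
  expect_s3_class(cmp, "sse_ml_comparison")
  expect_lte(cmp$constrained$loglik, cmp$full$loglik + 1e-6)
  expect_equal(cmp$lrt$df, 2)
  expect_equal(cmp$constrained$n_free, 4)
  expect_equal(cmp$full$n_free, 6)
  expect_true(cmp$lrt$p >= 0 && cmp$lrt$p <= 1)
  expect_equal(unname(cmp$constrained$par["lambda0"]),
               unname(cmp$constrained$par["lambda1"]))
  # constraints to constants
  one <- fit_sse_ml(sim$tree, xs, "bisse",
                    constraints = c("lambda1==lambda0", "mu0==0", "mu1==0",
                                    "q10==q01"),
                    n_starts = 1, fast = TRUE)
  expect_equal(one$constrained$n_free, 2)
  expect_equal(unname(one$constrained$par["mu0"]), 0)
})

test_that("SSE MCMC recovers its exponential prior with likelihood off", {
  set.seed(67)
  sim <- simulate_bd_tree(0.25, 0.05, stop = list(n_tips = 20), seed = 67)
  xs <- setNames(as.character(rbinom(20, 1, 0.5)), sim$tree$tip.label)
  r <- 0.1
  post <- sse_mcmc(sim$tree, xs, "bisse", r = r, n_gen = 3000, seed = 68,
                   use_lik = FALSE)
  expect_equal(post$burnin, 300)
  for (nm in post$par_names) {
    v <- post$samples[[nm]]
    se <- sd(v) / sqrt(viviphy:::.ess(v))
    expect_lt(abs(mean(v) - 2 * r), 3 * se)
  }
  # net diversification is definitional on the samples
  nd <- net_diversification(post)
  d0 <- post$samples$lambda0 - post$samples$mu0
  expect_equal(nd$mean[nd$state == "0"], mean(d0))
  expect_equal(nd$lower95[nd$state == "0"],
               unname(quantile(d0, 0.025)))
})

test_that("sampling fractions are computed and propagated", {
  expect_equal(sampling_fraction(79, 79), 1)
  expect_equal(sampling_fraction(100, 250), 0.4)
  expect_error(sampling_fraction(10, 5), "n_scored")
  expect_error(sampling_fraction(0, 5), "n_scored")
})
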