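test_that("Q matrix constructors respect constraint patterns", {
  Qer <- mk_q_matrix(0.5, "ER", 2)
  expect_equal(unname(rowSums(Qer)), c(0, 0))
  expect_equal(Qer[1, 2], Qer[2, 1])

  Qard <- mk_q_matrix(c(0.3, 0.7), "ARD", 2)
  expect_equal(Qard[1, 2], 0.3)
  expect_equal(Qard[2, 1], 0.7)

  Qsym3 <- mk_q_matrix(c(1, 2, 3), "SYM", 3)
  expect_equal(Qsym3[1, 2], Qsym3[2, 1])
  expect_equal(Qsym3[2, 3], Qsym3[3, 2])
  expect_error(mk_q_matrix(c(1, 2), "ER", 2), "needs 1")
  expect_error(mk_q_matrix(-1, "ER", 2), "non-negative")
  expect_equal(mk_n_rates("SYM", 3), 3L)
  expect_equal(mk_n_rates("ARD", 3), 6L)
})

test_that("transition probability rows sum to 1 for random valid Q", {
  set.seed(4)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    Q <- mk_q_matrix(runif(mk_n_rates("ARD", k), 0.05, 2), "ARD", k)
    P <- transition_prob(Q, runif(1, 0.01, 5))
    expect_equal(unname(rowSums(P)), rep(1, k), tolerance = 1e-10)
    expect_true(all(P >= 0))
  }
})

test_that("pruning likelihood matches the 2-tip closed form", {
  tr <- cherry()
  Q <- mk_q_matrix(0.5, "ER", 2, c("0", "1"))
  ll <- tip_likelihood(tr, c(A = "0", B = "0"), Q)
  expect_equal(exp(ll), two_tip_lik_oracle(0.5, 1, 1, 1, 1), tolerance = 1e-10)
  expect_equal(exp(ll), 0.283834, tolerance = 1e-6)

  # no evolution: only the prior mass of the shared state remains
  Q0 <- mk_q_matrix(1e-12, "ER", 2, c("0", "1"))
  expect_equal(exp(tip_likelihood(tr, c(A = "0", B = "0"), Q0)), 0.5,
               tolerance = 1e-9)

  # asymmetric branch lengths and states, against the same oracle
  tr2 <- parse_tree(text = "(A:0.4,B:2.3);")
  ll2 <- tip_likelihood(tr2, c(A = "0", B = "1"), Q)
  expect_equal(exp(ll2), two_tip_lik_oracle(0.5, 0.4, 2.3, 1, 2),
               tolerance = 1e-10)
})

test_that("likelihood agrees with an independent implementation", {
  set.seed(11)
  tr <- simulate_tree(40, "yule", root_age = 2)
  sim <- simulate_binary_trait(tr, mk_q_matrix(c(0.6, 0.3), "ARD", 2), seed = 2)
  Q <- mk_q_matrix(c(0.5, 0.25), "ARD", 2, c("0", "1"))
  mine <- tip_likelihood(tr, sim$states, Q)
  ref <- phytools::fitMk(tr, sim$states, model = "ARD", pi = "equal",
                         fixedQ = matrix(c(-0.5, 0.5, 0.25, -0.25), 2, 2,
                                         byrow = TRUE,
                                         dimnames = list(c("0", "1"),
                                                         c("0", "1"))))
  expect_equal(mine, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
})

test_that("ML fit attains the closed-form likelihood optimum on 2-tip trees", {
  # On a cherry the ER likelihood is monotone in q (boundary optima), so
  # the check is on the achieved likelihood against a dense grid of the
  # closed form rather than on the rate itself.
  tr <- parse_tree(text = "(A:1,B:1);")
  grid <- exp(seq(log(1e-8), log(1e3), length.out = 4000))

  # different tips: supremum log(0.25) as q -> Inf
  fit_diff <- fit_mk(tr, c(A = "0", B = "1"), "ER")
  ll_grid2 <- max(vapply(grid, function(q)
    log(two_tip_lik_oracle(q, 1, 1, 1, 2)), numeric(1)))
  expect_gte(fit_diff$loglik, ll_grid2 - 1e-4)
  expect_equal(fit_diff$loglik, log(0.25), tolerance = 1e-4)
  expect_equal(fit_diff$AIC, -2 * fit_diff$loglik + 2)
})

test_that("model nesting holds and monomorphic data are rejected", {
  set.seed(21)
  tr <- simulate_tree(80, "yule", root_age = 1)
  sim <- simulate_binary_trait(tr, mk_q_matrix(c(1.5, 0.7), "ARD", 2), seed = 5)
  er <- fit_mk(tr, sim$states, "ER")
  ard <- fit_mk(tr, sim$states, "ARD")
  expect_gte(ard$loglik, er$loglik - 1e-6)

  mono <- stats::setNames(rep("0", 80), tr$tip.label)
  expect_error(fit_mk(tr, mono, "ER"), "invariant")
})

test_that("fitted rates match an independent ML fitter", {
  set.seed(31)
  tr <- simulate_tree(120, "yule", root_age = 1)
  sim <- simulate_binary_trait(tr, mk_q_matrix(c(1.2, 0.5), "ARD", 2), seed = 6)
  mine <- fit_mk(tr, sim$states, "ARD")
  ref <- phytools::fitMk(tr, sim$states, model = "ARD", pi = "equal")
  expect_equal(mine$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
})

test_that("Akaike weights renormalise AIC differences", {
  w <- aic_weights(c(455.2, 455.2, 438.6))
  expect_equal(round(w, 5), c(0.00025, 0.00025, 0.99950))
  expect_equal(aic_weights(c(100, 100, 100)), rep(1 / 3, 3))
  expect_equal(aic_weights(c(10, 12)), c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_equal(sum(aic_weights(runif(5, 100, 200))), 1, tolerance = 1e-12)
})

test_that("model comparison selects the minimal-AIC model", {
  set.seed(41)
  tr <- simulate_tree(60, "yule", root_age = 1)
  sim <- simulate_binary_trait(tr, mk_q_matrix(1, "ER", 2), seed = 7)
  fits <- list(ER = fit_mk(tr, sim$states, "ER"),
               ARD = fit_mk(tr, sim$states, "ARD"))
  comp <- compare_models(fits)
  expect_equal(sum(comp$weight), 1, tolerance = 1e-12)
  expect_equal(attr(comp, "selected"), comp$model[which.min(comp$AIC)])
  # mismatched data refuse to compare
  sim2 <- simulate_binary_trait(tr, mk_q_matrix(1, "ER", 2), seed = 8)
  fits2 <- list(ER = fits$ER, ARD = fit_mk(tr, sim2$states, "ARD"))
  expect_error(compare_models(fits2), "different data")
})

test_that("lambda transform preserves depths and has the right endpoints", {
  tr <- parse_tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(lambda_transform(tr, 1)$edge.length, tr$edge.length)

  t0 <- lambda_transform(tr, 0)
  internal <- t0$edge[, 2] > ape::Ntip(t0)
  expect_equal(t0$edge.length[internal], 0)
  expect_equal(unname(node_depths(t0)[1:3]), rep(2, 3))

  th <- lambda_transform(tr, 0.5)
  expect_equal(unname(node_depths(th)[1:3]), rep(2, 3))
  expect_error(lambda_transform(tr, 1.5), "0, 1")
})

test_that("lambda likelihood is continuous in lambda", {
  set.seed(51)
  tr <- simulate_tree(50, "yule", root_age = 1)
  sim <- simulate_binary_trait(tr, mk_q_matrix(1, "ER", 2), seed = 9)
  Q <- mk_q_matrix(1, "ER", 2, c("0", "1"))
  ll <- function(lam) tip_likelihood(lambda_transform(tr, lam), sim$states, Q)
  for (lam in c(0.2, 0.5, 0.8)) {
    expect_lt(abs(ll(lam) - ll(lam + 1e-6)), 1e-3)
  }
})

test_that("lambda fit recovers signal and its absence on one replicate", {
  set.seed(61)
  tr <- simulate_tree(300, "yule", root_age = 1)
  sim <- simulate_binary_trait(tr, mk_q_matrix(1.5, "ER", 2), seed = 10)
  fit <- fit_lambda(tr, sim$states)
  expect_gte(fit$loglik, fit$loglik0 - 1e-9)
  expect_gt(fit$lambda, 0.5)

  shuffled <- stats::setNames(sample(sim$states), names(sim$states))
  fit0 <- fit_lambda(tr, shuffled)
  expect_lt(fit0$lambda, 0.5)
  expect_error(fit_lambda(tr, stats::setNames(rep("0", 300), tr$tip.label)),
               "binary")
})
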