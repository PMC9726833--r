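small_problem <- function(seed = 1, n_tips = 60) {
  tr <- simulate_tree(n_tips, "yule", root_age = 1, seed = seed)
  sim <- simulate_ecological_dataset(
    tr,
    factors = list(activity = c("Diurnal", "Obligate nocturnal")),
    effects = list(activity = 2), intercept = 0,
    sig2_phylo = 0.5, sig2_individual = 0.25, sig2_residual = 0.5,
    seed = seed + 100)
  list(tree = tr, sim = sim)
}

test_that("design matrices are treatment-coded against declared references", {
  pb <- small_problem()
  spec <- pglmm_spec("length_raw", "gaussian", fixed = "activity",
                     references = c(activity = "Diurnal"))
  d <- build_design(pb$sim$specimens, pb$tree, spec)
  expect_equal(colnames(d$X), c("(Intercept)", "activityObligate nocturnal"))
  expect_true(all(d$X[, 1] == 1))
  expect_equal(d$n, nrow(pb$sim$specimens))
  expect_equal(d$m, length(unique(pb$sim$specimens$species)))
  # row -> species incidence: every specimen maps to exactly one species
  expect_true(all(d$species_idx %in% seq_len(d$m)))
  expect_equal(d$species[d$species_idx], pb$sim$specimens$species)
  expect_equal(dim(d$C), c(d$m, d$m))

  # intercept-only model
  spec0 <- pglmm_spec("length_raw", "gaussian")
  expect_equal(colnames(build_design(pb$sim$specimens, pb$tree, spec0)$X),
               "(Intercept)")

  # unseen reference level and missing species are rejected
  bad <- spec
  bad$references <- c(activity = "Lunar")
  expect_error(build_design(pb$sim$specimens, pb$tree, bad), "reference level")
  orphan <- pb$sim$specimens
  orphan$species[1] <- "not_a_tip"
  expect_error(build_design(orphan, pb$tree, spec), "absent from tree")
})

test_that("threshold design requires a 0/1 response", {
  pb <- small_problem()
  spec <- pglmm_spec("length_raw", "threshold", fixed = "activity")
  expect_error(build_design(pb$sim$specimens, pb$tree, spec), "0/1")
})

test_that("pMCMC is twice the smaller tail, floored at 2/N", {
  expect_equal(pmcmc(c(rep(1, 500), rep(-1, 500))), 1.0)
  expect_equal(pmcmc(rep(1, 1000)), 0.002)
  expect_equal(pmcmc(c(rep(1, 975), rep(-1, 25))), 0.05)
  expect_error(pmcmc(1), "at least 2")
})

test_that("PSRF is 1 for identical chains and large for separated chains", {
  set.seed(2)
  x <- matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "a"))
  expect_equal(unname(gelman_rubin(list(x, x, x))), 1.0, tolerance = 1e-3)

  y <- matrix(rnorm(5000, 5), ncol = 1, dimnames = list(NULL, "a"))
  psrf <- gelman_rubin(list(x, y))
  expect_gt(unname(psrf), 1.1)

  # longhand oracle for the classic (unadjusted) PSRF
  n <- nrow(x)
  W <- (var(x[, 1]) + var(y[, 1])) / 2
  B <- n * var(c(mean(x), mean(y)))
  expect_equal(unname(psrf), sqrt(((n - 1) / n * W + B / n) / W),
               tolerance = 1e-12)
  # coda applies a small-sample df adjustment; both must agree on the verdict
  ml <- coda::mcmc.list(coda::mcmc(x), coda::mcmc(y))
  ref <- coda::gelman.diag(ml, autoburnin = FALSE)$psrf[, 1]
  expect_gt(unname(ref), 1.1)
  expect_error(gelman_rubin(list(x)), "two chains")
})

test_that("ESS of white noise is close to the chain length", {
  set.seed(3)
  x <- matrix(rnorm(4000), ncol = 1, dimnames = list(NULL, "a"))
  e <- ess(list(x))
  expect_gt(unname(e), 0.8 * 4000)
  expect_lt(unname(e), 1.2 * 4000)
})

test_that("summaries report means, CIs, significance and DIC", {
  const <- matrix(c(rep(2, 200), rep(100, 200)), ncol = 2,
                  dimnames = list(NULL, c("(Intercept)", "deviance")))
  s <- summarize_model(coda::mcmc.list(coda::mcmc(const), coda::mcmc(const)))
  row <- s$table[s$table$parameter == "(Intercept)", ]
  expect_equal(row$mean, 2)
  expect_equal(row$l95, 2)
  expect_equal(row$u95, 2)
  expect_true(row$significant)  # CI [2,2] excludes zero
  expect_equal(s$DIC, 100)      # constant deviance: no effective parameters
})

test_that("Gibbs sampler reproduces the conjugate posterior without random effects", {
  # tiny fixed-effects-only regression; the exact posterior of beta given
  # sigma^2 is available in closed form, and with a tight prior on the
  # variance components the mixed sampler should match it closely
  set.seed(4)
  n <- 20
  x <- rnorm(n)
  y <- 1 + 2 * x + rnorm(n, 0, 0.5)
  tr <- simulate_tree(n, "yule", root_age = 1, seed = 5)
  dat <- data.frame(species = tr$tip.label, y = y, x = x)
  # continuous covariate smuggled in via a 2-level coding is not possible;
  # instead check the intercept-only conjugate mean: beta | y ~ N(ybar, s/n)
  spec <- pglmm_spec("y", "gaussian", total = 6000, burnin = 1000, thin = 5,
                     chains = 2)
  fit <- run_pglmm(dat, tr, spec, seed = 6)
  pooled <- do.call(rbind, lapply(fit$chains, as.matrix))
  b0 <- pooled[, "(Intercept)"]
  tot_var <- pooled[, "var_phylo"] + pooled[, "var_individual"] +
    pooled[, "var_residual"]
  expect_lt(abs(mean(b0) - mean(y)), 3 * sd(y) / sqrt(n))
  # posterior total variance tracks the sample variance
  expect_lt(abs(mean(tot_var) - var(y)) / var(y), 0.75)
})

test_that("threshold liabilities always respect the observation sign", {
  pb <- small_problem(seed = 7)
  spec <- pglmm_spec("presence", "threshold", fixed = "activity",
                     references = c(activity = "Diurnal"),
                     total = 300, burnin = 100, thin = 2, chains = 1)
  d <- build_design(pb$sim$specimens, pb$tree, spec)
  # direct check of the truncated draw used by the sampler
  set.seed(8)
  m <- rnorm(2000, 0, 2)
  yy <- rbinom(2000, 1, 0.5)
  l <- bristlephy:::rtrunc_liability(m, yy)
  expect_true(all(l[yy == 1] > 0))
  expect_true(all(l[yy == 0] <= 0))
})

test_that("chains are bit-reproducible given the seed", {
  pb <- small_problem(seed = 9)
  spec <- pglmm_spec("length_raw", "gaussian", fixed = "activity",
                     references = c(activity = "Diurnal"),
                     total = 400, burnin = 100, thin = 3, chains = 2)
  f1 <- run_pglmm(pb$sim$specimens, pb$tree, spec, seed = 10)
  f2 <- run_pglmm(pb$sim$specimens, pb$tree, spec, seed = 10)
  expect_identical(lapply(f1$chains, as.matrix), lapply(f2$chains, as.matrix))
})

test_that("backward elimination drops a pure-noise factor, keeps the signal", {
  set.seed(11)
  tr <- simulate_tree(80, "yule", root_age = 1, seed = 11)
  sim <- simulate_ecological_dataset(
    tr,
    factors = list(activity = c("Diurnal", "Obligate nocturnal"),
                   noise = c("lo", "hi")),
    effects = list(activity = 2.5, noise = 0), intercept = 0,
    sig2_phylo = 0.3, sig2_individual = 0.1, sig2_residual = 0.5, seed = 12)
  spec <- pglmm_spec("length_raw", "gaussian",
                     fixed = c("activity", "noise"),
                     references = c(activity = "Diurnal", noise = "lo"),
                     total = 1200, burnin = 300, thin = 3, chains = 2)
  out <- backward_eliminate(sim$specimens, tr, spec, seed = 13)
  expect_true("activity" %in% out$spec$fixed)
  expect_true("(Intercept)" %in% out$summary$table$parameter)
  if (nrow(out$trail)) expect_false("activity" %in% out$trail$dropped[out$trail$kept])
})
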