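test_that("endpoint-conditioned histories obey dwell and parity rules", {
  Q <- mk_q_matrix(1, "ER", 2)
  # equal endpoints with a negligible rate: a single unbroken segment
  h0 <- sample_branch_history(1, 1, 2, mk_q_matrix(1e-14, "ER", 2), seed = 1)
  expect_equal(nrow(h0), 1)
  expect_equal(h0$dwell, 2)

  set.seed(2)
  for (i in 1:200) {
    a <- sample(1:2, 1); b <- sample(1:2, 1)
    t <- runif(1, 0.1, 3)
    h <- sample_branch_history(a, b, t, Q)
    expect_equal(sum(h$dwell), t, tolerance = 1e-9)
    expect_true(all(h$dwell > 0))
    expect_equal(h$state[1], a)
    expect_equal(h$state[nrow(h)], b)
    if (nrow(h) > 1) expect_true(all(diff(h$state) != 0))
    # 2 states: change count parity is fixed by the endpoints
    expect_equal((nrow(h) - 1) %% 2, as.integer(a != b))
  }
  expect_error(sample_branch_history(1, 2, 1, mk_q_matrix(0, "ER", 2)),
               "impossible endpoint")
})

test_that("conditioned change counts match a fine-grid discrete-time oracle", {
  # ER q = 1, t = 1, a = b: oracle simulates a 1e4-step discrete-time chain
  # with flip probability q*dt and keeps chains that return to the start
  q <- 1; nstep <- 1e4
  set.seed(3)
  flips <- rbinom(4e4, nstep, q / nstep)
  oracle <- flips[flips %% 2 == 0]
  Q <- mk_q_matrix(q, "ER", 2)
  set.seed(4)
  draws <- replicate(2e4, nrow(sample_branch_history(1, 1, 1, Q)) - 1)
  se <- sqrt(var(draws) / length(draws) + var(oracle) / length(oracle))
  expect_lt(abs(mean(draws) - mean(oracle)), 3 * se)
})

test_that("node-state draws reproduce symmetry and exact enumeration", {
  tr <- cherry()
  Q <- mk_q_matrix(0.5, "ER", 2, c("0", "1"))
  d <- sample_node_states(tr, c(A = "0", B = "1"), Q, n = 10000, seed = 5)
  root_freq <- mean(d[3, ] == 1)
  expect_lt(abs(root_freq - 0.5), 0.015)

  # asymmetric 3-tip case vs brute-force enumeration over internal states
  tr3 <- parse_tree(text = "((A:0.6,B:1.1):0.4,C:1.5);")
  st <- c(A = "0", B = "1", C = "1")
  Q2 <- mk_q_matrix(c(0.8, 0.3), "ARD", 2, c("0", "1"))
  exact <- enumerate_node_posteriors(tr3, st, Q2)
  draws <- sample_node_states(tr3, st, Q2, n = 20000, seed = 6)
  for (node in 4:5) {
    p_hat <- mean(draws[node, ] == 1)
    p <- exact[node, 1]
    se <- sqrt(p * (1 - p) / 20000)
    expect_lt(abs(p_hat - p), max(3 * se, 1e-3))
  }
})

test_that("maps satisfy the character-map invariants", {
  set.seed(7)
  tr <- simulate_tree(30, "yule", root_age = 2)
  sim <- simulate_binary_trait(tr, mk_q_matrix(c(0.8, 0.4), "ARD", 2), seed = 8)
  mm <- run_simmap(tr, sim$states, model = "ARD", nsim = 25, seed = 9)
  expect_length(mm$maps, 25)
  for (map in mm$maps[1:5]) {
    h <- map$history
    for (e in seq_len(nrow(tr$edge))) {
      seg <- h[h$edge == e, ]
      expect_equal(sum(seg$dwell), tr$edge.length[e], tolerance = 1e-9)
      if (nrow(seg) > 1) expect_true(all(diff(seg$state) != 0))
      # the first state on an edge is the parent node's sampled state
      expect_equal(seg$state[1], map$node_states[tr$edge[e, 1]])
      expect_equal(seg$state[nrow(seg)], map$node_states[tr$edge[e, 2]])
    }
  }
  # determinism given seed
  mm2 <- run_simmap(tr, sim$states, model = "ARD", nsim = 25, seed = 9)
  expect_identical(mm$maps[[10]]$history, mm2$maps[[10]]$history)
})

test_that("summaries partition changes into gains and losses", {
  set.seed(10)
  tr <- simulate_tree(40, "yule", root_age = 2)
  sim <- simulate_binary_trait(tr, mk_q_matrix(0.6, "ER", 2), seed = 11)
  mm <- run_simmap(tr, sim$states, model = "ER", nsim = 60, seed = 12)
  s <- summarize_maps(mm)
  expect_equal(s$gains + s$losses, s$changes)
  expect_equal(s$mean_gains + s$mean_losses, s$mean_changes)
  expect_equal(unname(sum(s$time_proportions)), 1, tolerance = 1e-9)
  expect_true(all(abs(rowSums(s$node_posteriors) - 1) < 1e-9))
  expect_equal(s$root_confidence,
               max(s$node_posteriors[ape::Ntip(tr) + 1, ]))

  # identical tip states with a near-zero rate: essentially no change
  mono_st <- stats::setNames(rep("0", 40), tr$tip.label)
  mm2 <- run_simmap(tr, mono_st, Q = mk_q_matrix(1e-3, "ER", 2, c("0", "1")),
                    nsim = 40, seed = 13)
  s2 <- summarize_maps(mm2)
  expect_lt(s2$mean_changes, 0.5)
})

test_that("time-absent arithmetic matches a hand-built single map", {
  tr <- parse_tree(text = "((A:2,B:2):1,C:3);")  # total length 8
  map <- list(node_states = c(1, 1, 1, 1, 1),
              history = data.frame(
                edge = c(1, 2, 2, 3, 4),
                state = c(1, 1, 2, 1, 1),
                dwell = c(1, 1.5, 0.5, 2, 3)))
  maps <- structure(list(tree = tr, labels = c("absent", "present"),
                         Q = NULL, maps = list(map)),
                    class = "simmap_maps")
  s <- summarize_maps(maps, present_state = "present")
  expect_equal(unname(s$time_proportions["absent"]), 7.5 / 8)
  expect_equal(s$mean_changes, 1)
  expect_equal(s$mean_gains, 1)
})

test_that("density maps are bounded and consistent with dwell summaries", {
  set.seed(14)
  tr <- simulate_tree(25, "yule", root_age = 2)
  sim <- simulate_binary_trait(tr, mk_q_matrix(0.7, "ER", 2), seed = 15)
  mm <- run_simmap(tr, sim$states, model = "ER", nsim = 50, seed = 16)
  dm <- density_map(mm, bins = 50)
  expect_true(all(dm$table$prob >= 0 & dm$table$prob <= 1))
  # per-edge mean of the binned probabilities ~ mean dwell fraction
  dwell_frac <- vapply(seq_len(nrow(tr$edge)), function(e) {
    mean(vapply(mm$maps, function(m) {
      seg <- m$history[m$history$edge == e, ]
      sum(seg$dwell[seg$state == 2]) / sum(seg$dwell)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(max(abs(dm$edge_mean - dwell_frac)), 0.05)

  nwk <- write_density_newick(dm)
  expect_match(nwk, "&state_prob=")
  expect_equal(sort(parse_tree(text = gsub("\\[[^]]*\\]", "", nwk))$tip.label),
               sort(tr$tip.label))
})

test_that("forward simulation matches rate x tree-length expectation", {
  set.seed(17)
  tr <- simulate_tree(50, "yule", root_age = 1)
  q <- 0.8
  Q <- mk_q_matrix(q, "ER", 2)
  n_changes <- replicate(400, simulate_binary_trait(tr, Q)$n_changes)
  expected <- q * sum(tr$edge.length)  # aggregate leaving rate = q for ER-2
  se <- sd(n_changes) / sqrt(length(n_changes))
  expect_lt(abs(mean(n_changes) - expected), 3 * se + 0.02 * expected)
})
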