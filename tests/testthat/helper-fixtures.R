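# Shared fixtures and independent oracles used across test files.

cherry <- function() parse_tree(text = "(A:1,B:1);")

three_tip <- function() parse_tree(text = "((A:1,B:1):0.5,C:1.5);")

# exact 2-tip Mk likelihood for a symmetric 2-state model:
# P(same state after t) = 1/2 + 1/2 exp(-2qt), summed over root states
two_tip_lik_oracle <- function(q, t1, t2, s1, s2, pi = c(0.5, 0.5)) {
  p_same <- function(t) 0.5 + 0.5 * exp(-2 * q * t)
  p_diff <- function(t) 0.5 - 0.5 * exp(-2 * q * t)
  lik <- 0
  for (r in 1:2) {
    p1 <- if (r == s1) p_same(t1) else p_diff(t1)
    p2 <- if (r == s2) p_same(t2) else p_diff(t2)
    lik <- lik + pi[r] * p1 * p2
  }
  lik
}

# brute-force pairwise tip distances via root paths
pairwise_tip_dist <- function(tree) {
  n <- ape::Ntip(tree)
  paths <- lapply(seq_len(n), function(tip) {
    node <- tip
    dist <- 0
    out <- numeric(0)
    repeat {
      e <- match(node, tree$edge[, 2])
      if (is.na(e)) break
      dist <- dist + tree$edge.length[e]
      node <- tree$edge[e, 1]
      out[as.character(node)] <- dist  # distance from tip to this ancestor
    }
    out
  })
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    common <- intersect(names(paths[[i]]), names(paths[[j]]))
    # the MRCA minimises the summed tip-to-ancestor distance
    D[i, j] <- D[j, i] <- min(paths[[i]][common] + paths[[j]][common])
  }
  D
}

# exact marginal node-state posteriors by enumerating all internal-state
# assignments of a small tree (binary states, indices 1..k)
enumerate_node_posteriors <- function(tree, states, Q, pi = c(0.5, 0.5)) {
  k <- nrow(Q)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  tip_idx <- match(as.character(states[tree$tip.label]), colnames(Q))
  internal <- (ntip + 1):nnode
  grids <- rep(list(seq_len(k)), length(internal))
  combos <- as.matrix(expand.grid(grids))
  P_edges <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_prob(Q, tree$edge.length[e]))
  post <- matrix(0, nnode, k)
  total <- 0
  for (r in seq_len(nrow(combos))) {
    assign <- integer(nnode)
    assign[seq_len(ntip)] <- tip_idx
    assign[internal] <- combos[r, ]
    pr <- pi[assign[ntip + 1]]
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * P_edges[[e]][assign[tree$edge[e, 1]], assign[tree$edge[e, 2]]]
    }
    total <- total + pr
    post[cbind(seq_len(nnode), assign)] <- post[cbind(seq_len(nnode), assign)] + pr
  }
  post / total
}

# small specimen table for trait tests
specimen_fixture <- function() {
  data.frame(
    species = c("sp1", "sp1", "sp2", "sp2", "sp3"),
    sex = c("male", "female", "male", "unknown", "female"),
    upper_rictal = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    lorial = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    lower_rictal = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    narial = c(FALSE, FALSE, FALSE, FALSE, FALSE),
    interramal = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    mean_length = c(20, 22, 0, 5, 0),
    shape = c("Unbranched", "Branched", "Absent", "Unbranched", "Absent"),
    family = c("famA", "famA", "famB", "famB", "famB"),
    stringsAsFactors = FALSE
  )
}
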