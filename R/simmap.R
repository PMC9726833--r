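## Stochastic character mapping: sample full character histories conditional
## on tip data and a rate matrix, and summarise them (changes, gains/losses,
## state dwell proportions, node posteriors, density maps).

## Precompute everything reusable across maps: partial likelihoods and
## per-edge transition matrices in pre-order.
simmap_prep <- function(tree, states, Q, pi = "equal", state_labels = NULL) {
  if (is.null(state_labels) && !is.null(colnames(Q))) state_labels <- colnames(Q)
  tm <- mk_tip_matrix(tree, states, state_labels)
  k <- nrow(Q)
  if (k != length(tm$labels)) stop("Q dimension does not match state count")
  piv <- root_prior_vector(pi, Q, k)
  pr <- mk_prune(tree, tm$L, Q, piv, keep_partials = TRUE)
  list(tree = tree, Q = Q, pi = piv, labels = tm$labels, tipmat = tm$L,
       prune = pr, k = k)
}

#' Sample internal-node states conditional on tip data
#'
#' The root state is drawn proportionally to `pi_i * L_i` (partial
#' likelihood), then each child is drawn pre-order from the product of the
#' transition probability from its parent's sampled state and its own
#' partial likelihood.
#'
#' @inheritParams tip_likelihood
#' @param n Number of independent draws.
#' @param seed Optional RNG seed.
#' @return Integer matrix `(Ntip + Nnode) x n` of state indices (1-based
#'   into the state labels, attribute `"labels"`); tip rows repeat the
#'   observed states (sampled when a tip is uncertain).
#' @export
sample_node_states <- function(tree, states, Q, pi = "equal", n = 1,
                               seed = NULL, state_labels = NULL) {
  prep <- simmap_prep(tree, states, Q, pi, state_labels)
  if (!is.null(seed)) set.seed(seed)
  draw_node_states(prep, n)
}

draw_node_states <- function(prep, n = 1) {
  pr <- prep$prune
  edge <- pr$postorder_edge
  k <- prep$k
  nnode <- nrow(pr$partials)
  out <- matrix(0L, nnode, n)
  root <- pr$root
  wroot <- prep$pi * pr$partials[root, ]
  if (sum(wroot) <= 0) stop("zero likelihood at root; data impossible under Q")
  out[root, ] <- sample.int(k, n, replace = TRUE, prob = wroot)
  ## pre-order = reverse post-order
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    P <- pr$P[[e]]
    Lch <- pr$partials[ch, ]
    ## for each draw, child | parent-state
    pstates <- out[par, ]
    for (s in unique(pstates)) {
      idx <- which(pstates == s)
      w <- P[s, ] * Lch
      if (sum(w) <= 0) stop("impossible transition on edge ", e)
      out[ch, idx] <- sample.int(k, length(idx), replace = TRUE, prob = w)
    }
  }
  attr(out, "labels") <- prep$labels
  out
}

#' Sample an endpoint-conditioned character history along one branch
#'
#' Exact draw of a continuous-time Markov path of duration `t` conditioned
#' on starting in state `a` and ending in state `b`, by uniformization: the
#' number of candidate jumps is drawn from its endpoint-conditioned
#' distribution under a dominating Poisson process of rate
#' `mu = max(-diag(Q))`, jump states are drawn from the conditioned jump
#' chain, and virtual (self) jumps are discarded.
#'
#' @param a,b 1-based start and end state indices.
#' @param t Branch duration (> 0).
#' @param Q Rate matrix.
#' @param seed Optional RNG seed.
#' @return Data frame with columns `state` (index) and `dwell`; dwell times
#'   sum to `t` and consecutive states differ.
#' @export
sample_branch_history <- function(a, b, t, Q, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(Q)
  mu <- max(-diag(Q))
  if (mu <= 0 || t <= 0) {
    if (a != b) stop("impossible endpoint pair: no rate, a != b")
    return(data.frame(state = a, dwell = t))
  }
  R <- diag(k) + Q / mu
  Pab <- transition_prob(Q, t)[a, b]
  if (Pab <= 0) stop("impossible endpoint pair (transition probability 0)")
  ## draw number of uniformization jumps n | endpoints
  nmax <- max(20, ceiling(mu * t + 12 * sqrt(mu * t)))
  Rpow <- vector("list", nmax + 1L)
  Rpow[[1]] <- diag(k)
  for (i in seq_len(nmax)) Rpow[[i + 1]] <- Rpow[[i]] %*% R
  logpois <- stats::dpois(0:nmax, mu * t, log = TRUE)
  wn <- exp(logpois) * vapply(0:nmax, function(n) Rpow[[n + 1]][a, b], numeric(1))
  wn <- wn / sum(wn)
  n <- sample.int(nmax + 1L, 1L, prob = wn) - 1L
  if (n == 0L) return(data.frame(state = a, dwell = t))
  times <- sort(stats::runif(n, 0, t))
  ## conditioned jump-chain states
  sts <- integer(n)
  cur <- a
  for (i in seq_len(n)) {
    rem <- n - i
    w <- R[cur, ] * vapply(seq_len(k), function(j) Rpow[[rem + 1]][j, b], numeric(1))
    sts[i] <- if (rem == 0L) b else sample.int(k, 1L, prob = w)
    cur <- sts[i]
  }
  ## collapse virtual jumps into segments
  path_states <- c(a, sts)
  path_times <- c(0, times, t)
  keep <- c(TRUE, diff(path_states) != 0)
  seg_states <- path_states[keep]
  seg_starts <- path_times[c(which(keep), length(path_times))]
  data.frame(state = seg_states, dwell = diff(seg_starts))
}

#' Generate stochastic character maps
#'
#' Draws `nsim` full character histories conditional on tip data, with the
#' rate matrix either supplied or fixed at its ML estimate under `model`
#' (the empirical approach: no resampling of Q between maps).
#'
#' @inheritParams fit_mk
#' @param nsim Number of maps.
#' @param seed RNG seed (reproducible given seed).
#' @param Q Optional rate matrix; when `NULL`, [fit_mk()] is run first.
#' @return Object of class `"simmap_maps"`: list with `tree`, `labels`,
#'   `Q`, and `maps` — one entry per draw, each holding `node_states` and a
#'   data frame `history` (edge, state, dwell) in the tree's edge order.
#' @export
run_simmap <- function(tree, states, model = "ER", nsim = 10000, seed = 1L,
                       Q = NULL, pi = "equal", state_labels = NULL, ...) {
  if (is.null(Q)) {
    fit <- fit_mk(tree, states, model = model, pi = pi,
                  state_labels = state_labels, ...)
    Q <- fit$Q
  }
  prep <- simmap_prep(tree, states, Q, pi, state_labels)
  set.seed(seed)
  nodes <- draw_node_states(prep, nsim)
  edge <- tree$edge
  elen <- tree$edge.length
  maps <- vector("list", nsim)
  for (m in seq_len(nsim)) {
    segs <- vector("list", nrow(edge))
    ns <- nodes[, m]
    for (e in seq_len(nrow(edge))) {
      h <- sample_branch_history(ns[edge[e, 1]], ns[edge[e, 2]], elen[e], Q)
      h$edge <- e
      segs[[e]] <- h
    }
    hist <- do.call(rbind, segs)
    maps[[m]] <- list(node_states = ns, history = hist[, c("edge", "state", "dwell")])
  }
  structure(list(tree = tree, labels = prep$labels, Q = Q, maps = maps,
                 seed = seed), class = "simmap_maps")
}

map_change_counts <- function(map, k = 2) {
  ## transitions within edges: consecutive segments on the same edge
  h <- map$history
  from <- h$state[-nrow(h)]; to <- h$state[-1]
  same_edge <- h$edge[-nrow(h)] == h$edge[-1]
  cbind(from = from[same_edge], to = to[same_edge])
}

#' Summarise a set of stochastic maps
#'
#' @param maps A `"simmap_maps"` object (or list of them over the same tree,
#'   which are pooled).
#' @param present_state Label counted as "present" for the gain/loss
#'   direction (default the second state label, i.e. `"1"` for 0/1 data).
#' @return Class `"simmap_summary"`: list with `n_maps`, `mean_changes`,
#'   `mean_gains`, `mean_losses`, `time_proportions` (mean proportion of
#'   total tree time per state), `node_posteriors` (nodes x states),
#'   `root_state` (modal root state) and `root_confidence`.
#' @export
summarize_maps <- function(maps, present_state = NULL) {
  if (inherits(maps, "simmap_maps")) maps <- list(maps)
  if (!length(maps)) stop("no maps supplied")
  ref <- maps[[1]]$tree
  for (m in maps) {
    if (!identical(sort(m$tree$tip.label), sort(ref$tip.label))) {
      stop("maps were generated on different trees (tip sets differ)")
    }
  }
  labels <- maps[[1]]$labels
  k <- length(labels)
  if (is.null(present_state)) present_state <- labels[min(2, k)]
  pres_idx <- match(present_state, labels)
  if (is.na(pres_idx)) stop("present_state not among state labels")
  total_time <- sum(ref$edge.length)
  n_nodes <- ape::Ntip(ref) + ref$Nnode
  root_node <- ape::Ntip(ref) + 1L
  changes <- gains <- losses <- numeric(0)
  timeprop <- NULL
  node_counts <- matrix(0, n_nodes, k)
  n_maps <- 0L
  for (set in maps) {
    for (map in set$maps) {
      n_maps <- n_maps + 1L
      cc <- map_change_counts(map)
      changes <- c(changes, nrow(cc))
      gains <- c(gains, sum(cc[, "to"] == pres_idx))
      losses <- c(losses, sum(cc[, "from"] == pres_idx))
      tp <- vapply(seq_len(k), function(s)
        sum(map$history$dwell[map$history$state == s]), numeric(1)) /
        sum(map$history$dwell)
      timeprop <- rbind(timeprop, tp)
      node_counts[cbind(seq_len(n_nodes), map$node_states)] <-
        node_counts[cbind(seq_len(n_nodes), map$node_states)] + 1
    }
  }
  node_post <- node_counts / n_maps
  colnames(node_post) <- labels
  tp_mean <- colMeans(timeprop)
  names(tp_mean) <- labels
  root_post <- node_post[root_node, ]
  root_state <- labels[which.max(root_post)]
  structure(list(
    n_maps = n_maps,
    mean_changes = mean(changes),
    mean_gains = mean(gains),
    mean_losses = mean(losses),
    changes = changes, gains = gains, losses = losses,
    time_proportions = tp_mean,
    node_posteriors = node_post,
    root_state = root_state,
    root_confidence = unname(root_post[root_state]),
    present_state = present_state,
    labels = labels,
    total_tree_time = total_time
  ), class = "simmap_summary")
}

#' @export
print.simmap_summary <- function(x, ...) {
  cat("Stochastic map summary over", x$n_maps, "maps\n")
  cat(sprintf("  mean changes: %.2f (gains %.2f / losses %.2f; present = '%s')\n",
              x$mean_changes, x$mean_gains, x$mean_losses, x$present_state))
  cat("  time proportions:",
      paste(sprintf("%s %.3f", names(x$time_proportions), x$time_proportions),
            collapse = ", "), "\n")
  cat(sprintf("  root: '%s' with confidence %.3f\n", x$root_state,
              x$root_confidence))
  invisible(x)
}

#' Time-resolved posterior density of a state along every edge
#'
#' Each edge is discretised into `bins` equal intervals; the value at a bin
#' is the fraction of maps in `present_state` at the bin midpoint.
#'
#' @inheritParams summarize_maps
#' @param bins Bins per edge.
#' @return Class `"density_map"`: list with `table` (edge, bin, time at bin
#'   midpoint from the edge start, prob) and the tree; see
#'   [write_density_newick()] for the annotated-Newick export.
#' @export
density_map <- function(maps, bins = 100, present_state = NULL) {
  if (inherits(maps, "simmap_maps")) maps <- list(maps)
  labels <- maps[[1]]$labels
  if (is.null(present_state)) present_state <- labels[min(2, length(labels))]
  pres_idx <- match(present_state, labels)
  tree <- maps[[1]]$tree
  n_edge <- nrow(tree$edge)
  counts <- matrix(0, n_edge, bins)
  n_maps <- 0L
  mids <- (seq_len(bins) - 0.5) / bins
  for (set in maps) for (map in set$maps) {
    n_maps <- n_maps + 1L
    h <- map$history
    for (e in seq_len(n_edge)) {
      seg <- h[h$edge == e, ]
      bounds <- cumsum(seg$dwell)
      tlen <- bounds[length(bounds)]
      at <- findInterval(mids * tlen, bounds, left.open = FALSE) + 1L
      at[at > nrow(seg)] <- nrow(seg)
      counts[e, ] <- counts[e, ] + (seg$state[at] == pres_idx)
    }
  }
  prob <- counts / n_maps
  tab <- data.frame(
    edge = rep(seq_len(n_edge), each = bins),
    bin = rep(seq_len(bins), n_edge),
    rel_position = rep(mids, n_edge),
    prob = as.vector(t(prob))
  )
  structure(list(tree = tree, table = tab, bins = bins,
                 present_state = present_state,
                 edge_mean = rowMeans(prob)), class = "density_map")
}

#' Write a density map as annotated Newick
#'
#' Each edge carries a comment tag `[&state_prob=p]` with its mean
#' probability of the mapped state, readable by annotation-aware viewers.
#'
#' @param dm A `"density_map"`.
#' @param file Optional output path.
#' @return The annotated Newick string (invisibly when writing to file).
#' @export
write_density_newick <- function(dm, file = NULL) {
  tree <- dm$tree
  probs <- dm$edge_mean
  ntip <- ape::Ntip(tree)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node) {
    inc <- match(node, tree$edge[, 2])
    suffix <- if (!is.na(inc)) {
      sprintf(":%s[&state_prob=%.6g]", format(tree$edge.length[inc], digits = 12),
              probs[inc])
    } else ""
    if (node <= ntip) return(paste0(tree$tip.label[node], suffix))
    ch <- tree$edge[kids[[as.character(node)]], 2]
    paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")", suffix)
  }
  out <- paste0(rec(ntip + 1L), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Export map segments as a flat table
#'
#' @param maps A `"simmap_maps"` object.
#' @return Data frame with map index, edge id, segment state label, start
#'   and end time along the edge.
#' @export
map_segments <- function(maps) {
  stopifnot(inherits(maps, "simmap_maps"))
  out <- lapply(seq_along(maps$maps), function(m) {
    h <- maps$maps[[m]]$history
    starts <- stats::ave(h$dwell, h$edge,
                         FUN = function(d) cumsum(c(0, d[-length(d)])))
    data.frame(map = m, edge = h$edge, state = maps$labels[h$state],
               start = starts, end = starts + h$dwell)
  })
  do.call(rbind, out)
}
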