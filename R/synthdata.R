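## Seeded generators for every input the pipeline consumes, each returning
## its ground truth so downstream estimates can be checked against it.

#' Simulate an ultrametric tree
#'
#' Yule (pure-birth) or constant-rate birth-death tree conditioned on the
#' number of tips, rescaled to a chosen root (crown) age. The default age
#' of 108 time units mirrors the crown age of a large avian phylogeny; rate
#' estimates are then per-unit-time of that scale.
#'
#' @param n_tips Number of tips (>= 2).
#' @param model `"yule"` or `"birth-death"`.
#' @param birth,death Per-lineage rates (death ignored for `"yule"`).
#' @param root_age Crown age the tree is rescaled to.
#' @param seed Optional RNG seed.
#' @return An ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, model = c("yule", "birth-death"),
                          birth = 1, death = 0.5, root_age = 108,
                          seed = NULL) {
  model <- match.arg(model)
  if (n_tips < 2) stop("need at least 2 tips")
  if (!is.null(seed)) set.seed(seed)
  if (model == "yule") death <- 0
  tree <- ape::rphylo(n_tips, birth = birth, death = death)
  tree$edge.length <- tree$edge.length * (root_age / max(node_depths(tree)))
  tree
}

#' Simulate a pseudo-posterior set of perturbed trees
#'
#' Each replicate applies a Poisson-distributed number of random
#' nearest-neighbour interchanges to the base topology, jitters every edge
#' length log-normally, and is re-ultrametrised. `topology_moves = 0` and
#' `length_jitter_sd = 0` reproduce the base tree exactly.
#'
#' @param tree Base ultrametric `phylo`.
#' @param n Number of replicate trees.
#' @param topology_moves Mean number of NNI moves per replicate.
#' @param length_jitter_sd Standard deviation of the log-normal edge
#'   jitter (on the log scale).
#' @param seed Optional RNG seed.
#' @return A `multiPhylo` with provenance `"synthetic"`.
#' @export
simulate_tree_posterior <- function(tree, n, topology_moves = 2,
                                    length_jitter_sd = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reps <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- tree
    k <- stats::rpois(1, topology_moves)
    if (k > 0) {
      tr <- phangorn::rNNI(tr, moves = k)
      ## rNNI can drop or scramble lengths; restore a clock by redrawing
      ## them from the base tree's depth
      if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
    }
    if (length_jitter_sd > 0 || k > 0) {
      tr$edge.length <- tr$edge.length *
        stats::rlnorm(length(tr$edge.length), 0, max(length_jitter_sd, 1e-3))
      tr <- force_ultrametric(tr, method = "nnls")
      tr$edge.length <- tr$edge.length * (root_age(tree) / root_age(tr))
    }
    reps[[i]] <- tr
  }
  out <- structure(reps, class = "multiPhylo")
  attr(out, "provenance") <- "synthetic"
  out
}

#' Forward-simulate a binary character with its true history
#'
#' Evolves a 2-state Markov character from the root down the
#' lambda-transformed tree (Gillespie within each edge), recording the full
#' true character history. Segment dwell times are reported in the
#' untransformed tree's coordinates (rescaled per edge), so the truth is
#' directly comparable to maps inferred on the original tree.
#'
#' @param tree Ultrametric `phylo`.
#' @param Q 2-state rate matrix (see [mk_q_matrix()]).
#' @param lambda Signal attenuation in \[0, 1\]; 1 = evolve on the tree as
#'   is.
#' @param root_state Root state label (one of the Q state labels).
#' @param seed Optional RNG seed.
#' @return List: `states` (named tip vector of state labels), `history`
#'   (data frame edge/state/dwell on the original tree), `n_changes`,
#'   `node_states`, `lambda`, `Q`.
#' @export
simulate_binary_trait <- function(tree, Q, lambda = 1, root_state = NULL,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(Q)
  labels <- colnames(Q)
  if (is.null(labels)) labels <- as.character(seq_len(k) - 1L)
  if (is.null(root_state)) root_state <- labels[1]
  root_idx <- match(root_state, labels)
  if (is.na(root_idx)) stop("root_state not a state of Q")
  tt <- lambda_transform(tree, lambda)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  node_state <- integer(nnode)
  node_state[ntip + 1L] <- root_idx
  ord <- stats::reorder(tree, "cladewise")
  edge_map <- match(paste(ord$edge[, 1], ord$edge[, 2]),
                    paste(tree$edge[, 1], tree$edge[, 2]))
  hist_list <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    orig_e <- edge_map[e]
    t_total <- tt$edge.length[orig_e]
    s <- node_state[par]
    segs <- list(); t_at <- 0
    repeat {
      rate <- -Q[s, s]
      dt <- if (rate <= 0) Inf else stats::rexp(1, rate)
      if (t_at + dt >= t_total) {
        segs[[length(segs) + 1L]] <- c(s, t_total - t_at)
        break
      }
      segs[[length(segs) + 1L]] <- c(s, dt)
      t_at <- t_at + dt
      pj <- Q[s, ]; pj[s] <- 0
      s <- sample.int(k, 1, prob = pj)
    }
    m <- do.call(rbind, segs)
    ## rescale dwell to the original edge length
    scale <- if (t_total > 0) tree$edge.length[orig_e] / t_total else 1
    hist_list[[orig_e]] <- data.frame(edge = orig_e, state = m[, 1],
                                      dwell = m[, 2] * scale)
    node_state[ch] <- s
  }
  history <- do.call(rbind, hist_list)
  changes <- sum(stats::ave(history$state, history$edge,
                            FUN = function(s) c(0, diff(s) != 0)))
  states <- stats::setNames(labels[node_state[seq_len(ntip)]], tree$tip.label)
  list(states = states, history = history, n_changes = changes,
       node_states = node_state, lambda = lambda, Q = Q, labels = labels)
}

#' Simulate a specimen-level ecological dataset with known truth
#'
#' Builds the dataset the mixed models consume: species get categorical
#' ecological traits, a phylogenetically correlated species effect
#' (covariance `sig2_phylo * C`), and each specimen gets an individual
#' effect and residual. The liability determines bristle presence
#' (`liability > 0`); the Gaussian response is returned both raw
#' (`length_raw`) and floored at zero (`length`), mimicking non-negative
#' length measurements. Family labels with heterogeneous sampling
#' fractions are attached for the downsampling analyses.
#'
#' @param tree Ultrametric `phylo` (species = tips).
#' @param factors Named list: factor name -> character vector of levels
#'   (first level = reference).
#' @param effects Named list: factor name -> numeric vector of effects per
#'   non-reference level (reference effect is 0).
#' @param intercept Intercept of the linear predictor.
#' @param sig2_phylo,sig2_individual,sig2_residual Variance components.
#' @param specimens_per_species Specimens per species.
#' @param n_families Number of synthetic family labels; sampling fractions
#'   are spread over \[0.1, 1\] to create over/under-represented families.
#' @param seed Optional RNG seed.
#' @return List with `specimens` (data frame), `species_table`, `richness`
#'   (family -> known species count implied by the fractions), and `truth`
#'   (beta vector, variance components, species liabilities, seed).
#' @export
simulate_ecological_dataset <- function(tree,
                                        factors = list(activity = c("Diurnal", "Obligate nocturnal")),
                                        effects = list(activity = 2),
                                        intercept = 0,
                                        sig2_phylo = 1,
                                        sig2_individual = 0.25,
                                        sig2_residual = 0.5,
                                        specimens_per_species = 2,
                                        n_families = 10,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  species <- tree$tip.label
  m <- length(species)
  ## categorical ecology, uniform over levels
  eco <- lapply(factors, function(lev) sample(lev, m, replace = TRUE))
  ## species effect u ~ N(0, sig2_phylo * C)
  C <- phylo_correlation(tree)[species, species]
  u <- if (sig2_phylo > 0) {
    as.vector(t(chol(C + diag(1e-10, m))) %*% stats::rnorm(m)) * sqrt(sig2_phylo)
  } else rep(0, m)
  ## family labels follow the tree: contiguous clades of tips
  cw <- stats::reorder(tree, "cladewise")
  tip_order <- cw$edge[cw$edge[, 2] <= m, 2]
  fam_of_tip <- integer(m)
  fam_of_tip[tip_order] <- cut(seq_len(m), breaks = n_families, labels = FALSE)
  family <- paste0("fam", fam_of_tip)
  fractions <- stats::setNames(seq(0.1, 1, length.out = n_families),
                               paste0("fam", seq_len(n_families)))
  sampled <- table(factor(family, levels = names(fractions)))
  richness <- pmax(round(as.integer(sampled) / fractions), as.integer(sampled))
  richness[as.integer(sampled) == 0] <- 1
  names(richness) <- names(fractions)
  ## design at species level
  beta <- numeric(0)
  eta_sp <- rep(intercept, m)
  for (f in names(factors)) {
    lev <- factors[[f]]
    eff <- c(0, effects[[f]])
    if (length(eff) != length(lev)) {
      stop("effects for ", f, " must have length ", length(lev) - 1L)
    }
    eta_sp <- eta_sp + eff[match(eco[[f]], lev)]
    b <- eff[-1]
    names(b) <- paste0(f, lev[-1])
    beta <- c(beta, b)
  }
  nspec <- specimens_per_species
  n <- m * nspec
  sp_idx <- rep(seq_len(m), each = nspec)
  w <- stats::rnorm(n, 0, sqrt(sig2_individual))
  e <- stats::rnorm(n, 0, sqrt(sig2_residual))
  liability <- eta_sp[sp_idx] + u[sp_idx] + w + e
  specimens <- data.frame(
    specimen = paste0(species[sp_idx], "_s", rep(seq_len(nspec), m)),
    species = species[sp_idx],
    family = family[sp_idx],
    presence = as.integer(liability > 0),
    length_raw = liability,
    length = pmax(liability, 0),
    stringsAsFactors = FALSE
  )
  for (f in names(factors)) specimens[[f]] <- eco[[f]][sp_idx]
  species_table <- data.frame(species = species, family = family,
                              stringsAsFactors = FALSE)
  for (f in names(factors)) species_table[[f]] <- eco[[f]]
  list(
    specimens = specimens,
    species_table = species_table,
    richness = richness,
    truth = list(intercept = intercept, beta = beta,
                 sig2_phylo = sig2_phylo, sig2_individual = sig2_individual,
                 sig2_residual = sig2_residual, species_effect = u,
                 liability = liability, seed = seed)
  )
}
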