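## Mk (k-state continuous-time Markov) machinery: likelihood by Felsenstein
## pruning, ML rate fitting under ER/SYM/ARD constraints, AIC model
## selection, and a discrete-coherent Pagel's-lambda signal estimate.

#' Build an Mk rate matrix under a named constraint model
#'
#' @param rates Free-rate vector: ER 1 rate; SYM one per unordered state
#'   pair (upper triangle, row-wise); ARD one per ordered pair (row-wise,
#'   off-diagonal).
#' @param model `"ER"`, `"SYM"` or `"ARD"`.
#' @param k Number of states.
#' @param states Optional state labels (length `k`).
#' @return A `k x k` matrix with rows summing to zero, class `"qmatrix"`,
#'   with attributes `model` and `rates`.
#' @export
mk_q_matrix <- function(rates, model = c("ER", "SYM", "ARD"), k = 2,
                        states = NULL) {
  model <- match.arg(model)
  if (any(rates < 0)) stop("rates must be non-negative")
  idx <- mk_rate_index(model, k)
  np <- max(idx, na.rm = TRUE)
  if (length(rates) != np) {
    stop("model ", model, " with k=", k, " needs ", np, " rate(s), got ",
         length(rates))
  }
  Q <- matrix(0, k, k)
  off <- which(!is.na(idx))
  Q[off] <- rates[idx[off]]
  diag(Q) <- -rowSums(Q)
  if (is.null(states)) states <- as.character(seq_len(k) - 1L)
  dimnames(Q) <- list(states, states)
  structure(Q, model = model, rates = rates, class = c("qmatrix", "matrix"))
}

## index matrix mapping off-diagonal cells to free-parameter slots
mk_rate_index <- function(model, k) {
  idx <- matrix(NA_integer_, k, k)
  if (model == "ER") {
    idx[row(idx) != col(idx)] <- 1L
  } else if (model == "SYM") {
    p <- 0L
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      p <- p + 1L
      idx[i, j] <- idx[j, i] <- p
    }
  } else {
    p <- 0L
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i != j) { p <- p + 1L; idx[i, j] <- p }
    }
  }
  idx
}

#' Number of free rates of a constraint model
#' @inheritParams mk_q_matrix
#' @export
mk_n_rates <- function(model = c("ER", "SYM", "ARD"), k = 2) {
  model <- match.arg(model)
  switch(model, ER = 1L, SYM = as.integer(k * (k - 1) / 2),
         ARD = as.integer(k * (k - 1)))
}

#' Transition probability matrix exp(Q t)
#'
#' Two-state matrices use the closed form; larger matrices use the
#' eigendecomposition exponential.
#'
#' @param Q Rate matrix (rows sum to 0).
#' @param t Elapsed time (>= 0).
#' @return Stochastic matrix of the same dimension.
#' @export
transition_prob <- function(Q, t) {
  k <- nrow(Q)
  if (t == 0) return(diag(k))
  if (t < 0) {
    if (t < -1e-8) stop("negative elapsed time")
    return(diag(k))  # tolerate numerically-zero negatives from tree repair
  }
  if (k == 2L) {
    a <- Q[1, 2]; b <- Q[2, 1]; s <- a + b
    if (s <= 0) return(diag(2))
    e <- exp(-s * t)
    P <- matrix(c(b + a * e, b - b * e, a - a * e, a + b * e), 2, 2) / s
    P[P < 0] <- 0
    return(P)
  }
  P <- ape::matexpo(Q * t)
  P[P < 0] <- 0
  P / rowSums(P)
}

## normalize tip data into an Ntip x k likelihood matrix + state labels
mk_tip_matrix <- function(tree, states, state_labels = NULL) {
  ntip <- ape::Ntip(tree)
  if (is.matrix(states)) {
    if (is.null(rownames(states))) stop("tip matrix must have tip rownames")
    orphans <- setdiff(rownames(states), tree$tip.label)
    if (length(orphans)) stop("tips not in tree: ", paste(orphans, collapse = ", "))
    miss <- setdiff(tree$tip.label, rownames(states))
    if (length(miss)) stop("tips lacking states: ", paste(miss, collapse = ", "))
    L <- states[tree$tip.label, , drop = FALSE]
    labels <- colnames(L)
    if (is.null(labels)) labels <- as.character(seq_len(ncol(L)) - 1L)
    return(list(L = unname(as.matrix(L)), labels = labels))
  }
  if (is.null(names(states))) stop("`states` must be named by tip label")
  orphans <- setdiff(names(states), tree$tip.label)
  if (length(orphans)) stop("tips not in tree: ", paste(orphans, collapse = ", "))
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss)) stop("tips lacking states: ", paste(miss, collapse = ", "))
  x <- as.character(states[tree$tip.label])
  labels <- state_labels
  if (is.null(labels)) labels <- sort(unique(x))
  if (!all(x %in% labels)) {
    stop("states outside declared labels: ",
         paste(setdiff(x, labels), collapse = ", "))
  }
  L <- matrix(0, ntip, length(labels))
  L[cbind(seq_len(ntip), match(x, labels))] <- 1
  list(L = L, labels = labels)
}

root_prior_vector <- function(pi, Q, k) {
  if (is.character(pi)) {
    pi <- match.arg(pi, c("equal", "stationary"))
    if (pi == "equal") return(rep(1 / k, k))
    ## stationary distribution: left null vector of Q
    v <- Re(eigen(t(Q))$vectors[, which.min(abs(Re(eigen(t(Q))$values)))])
    v <- abs(v)
    return(v / sum(v))
  }
  if (length(pi) != k || any(pi < 0)) stop("invalid root prior")
  pi / sum(pi)
}

## Felsenstein pruning pass. Returns log-likelihood and (optionally) the
## scaled partial-likelihood matrix over all nodes, for use by the mapper.
mk_prune <- function(tree, tipmat, Q, pi, keep_partials = FALSE) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  k <- nrow(Q)
  po <- stats::reorder(tree, "postorder")
  L <- matrix(1, nnode, k)
  L[seq_len(ntip), ] <- tipmat
  logscale <- 0
  edge <- po$edge; elen <- po$edge.length
  Plist <- vector("list", nrow(edge))
  done <- logical(nnode)
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    P <- transition_prob(Q, elen[e])
    Plist[[e]] <- P
    contrib <- as.vector(P %*% L[ch, ])
    L[par, ] <- L[par, ] * contrib
    m <- max(L[par, ])
    if (m < 1e-280) {  # guard hard underflow
      m <- max(m, .Machine$double.xmin)
    }
    if (m < 1e-4) {
      L[par, ] <- L[par, ] / m
      logscale <- logscale + log(m)
    }
  }
  root <- edge[nrow(edge), 1]
  lik <- sum(pi * L[root, ])
  ll <- log(lik) + logscale
  if (!keep_partials) return(list(loglik = ll))
  list(loglik = ll, partials = L, root = root, postorder_edge = edge,
       P = Plist, edge_length = elen)
}

#' Mk log-likelihood of tip data on a tree
#'
#' Felsenstein pruning: per-edge transition probabilities `exp(Q t)`
#' combined post-order, with the root prior `pi` applied at the root.
#'
#' @param tree A `phylo` with edge lengths.
#' @param states Named vector of tip states, or an Ntip x k matrix of tip
#'   state likelihoods (rownames = tips) for uncertain tips.
#' @param Q Rate matrix (see [mk_q_matrix()]).
#' @param pi Root prior: `"equal"` (default), `"stationary"`, or a
#'   probability vector of length k.
#' @param state_labels Optional explicit state labels.
#' @return Log-likelihood (numeric scalar).
#' @export
tip_likelihood <- function(tree, states, Q, pi = "equal", state_labels = NULL) {
  if (is.null(state_labels) && !is.null(colnames(Q))) state_labels <- colnames(Q)
  tm <- mk_tip_matrix(tree, states, state_labels)
  if (nrow(Q) != length(tm$labels)) {
    stop("Q dimension ", nrow(Q), " does not match ", length(tm$labels),
         " observed states")
  }
  piv <- root_prior_vector(pi, Q, nrow(Q))
  mk_prune(tree, tm$L, Q, piv)$loglik
}

#' Maximum-likelihood fit of an Mk model
#'
#' Bounded quasi-Newton optimisation on log rates with multiple restarts
#' (deterministic given `seed`).
#'
#' @inheritParams tip_likelihood
#' @param model Constraint model: `"ER"`, `"SYM"` or `"ARD"`.
#' @param n_restarts Random restarts beyond the heuristic start.
#' @param seed Seed controlling the restart draws.
#' @return An object of class `"mk_fit"`: list with `Q`, `rates`, `model`,
#'   `loglik`, `AIC`, `k`, `pi`, `states` (labels), `data_hash`,
#'   `convergence` diagnostics.
#' @export
fit_mk <- function(tree, states, model = c("ER", "SYM", "ARD"), pi = "equal",
                   n_restarts = 5, seed = 1L, state_labels = NULL) {
  model <- match.arg(model)
  tm <- mk_tip_matrix(tree, states, state_labels)
  k <- length(tm$labels)
  if (k < 2L) {
    stop("trait invariant; rates unidentifiable (only state: ",
         tm$labels, ")")
  }
  ## monomorphic check for hard-coded tips: every tip certain and identical
  hard <- apply(tm$L, 1, function(r) sum(r > 0) == 1L)
  if (all(hard)) {
    obs <- unique(apply(tm$L, 1, which.max))
    if (length(obs) < 2L) {
      stop("trait invariant; rates unidentifiable")
    }
  }
  np <- mk_n_rates(model, k)
  total_len <- sum(tree$edge.length)
  q0 <- max(1, k - 1) / total_len * k  # crude scale: ~1 expected change
  nll <- function(logr) {
    Q <- mk_q_matrix(exp(logr), model, k, tm$labels)
    piv <- root_prior_vector(pi, Q, k)
    ll <- mk_prune(tree, tm$L, Q, piv)$loglik
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  starts <- matrix(log(q0), n_restarts + 1L, np)
  ## restart jitter from a private RNG stream: must not disturb the
  ## caller's RNG state
  rng <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    matrix(stats::runif(n_restarts * np, -3, 3), n_restarts, np)
  })
  if (n_restarts > 0) starts[-1L, ] <- starts[-1L, , drop = FALSE] + rng
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- try(stats::optim(starts[s, ], nll, method = "L-BFGS-B",
                            lower = log(1e-9), upper = log(1e6),
                            control = list(factr = 1e4)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (is.null(best)) stop("Mk optimisation failed for all starts")
  rates <- exp(best$par)
  Q <- mk_q_matrix(rates, model, k, tm$labels)
  piv <- root_prior_vector(pi, Q, k)
  ll <- -best$value
  structure(list(
    Q = Q, rates = rates, model = model, loglik = ll,
    AIC = -2 * ll + 2 * np, n_par = np, k = k, pi = piv,
    states = tm$labels, tree_ntip = ape::Ntip(tree),
    data_hash = data_hash(tree, tm$L),
    convergence = list(restarts = n_restarts, code = best$convergence)
  ), class = "mk_fit")
}

data_hash <- function(tree, tipmat) {
  sum(tipmat * seq_along(tipmat)) + sum(tree$edge.length) + ape::Ntip(tree)
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk fit (", x$model, "), k = ", x$k, "\n", sep = "")
  cat("  log-likelihood:", format(x$loglik), " AIC:", format(x$AIC), "\n")
  cat("  rates:", paste(format(x$rates, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Akaike weights from AIC values
#'
#' `w_i = exp(-(AIC_i - min AIC)/2) / sum_j exp(-(AIC_j - min AIC)/2)`.
#'
#' @param aic Numeric vector of AIC values.
#' @return Weights summing to 1, same names as `aic`.
#' @export
aic_weights <- function(aic) {
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Compare fitted Mk models by AIC
#'
#' @param fits List of [fit_mk()] results on identical data.
#' @return Class `"mk_model_comparison"`: data frame with model, n_par,
#'   loglik, AIC, dAIC and Akaike weight, plus attribute `selected`
#'   (the minimal-AIC model).
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2L) stop("need at least two fits to compare")
  if (is.null(names(fits))) names(fits) <- vapply(fits, `[[`, "", "model")
  hashes <- vapply(fits, `[[`, numeric(1), "data_hash")
  if (any(abs(hashes - hashes[1]) > 1e-6 * max(1, abs(hashes[1])))) {
    stop("fits were made on different data; comparison is meaningless")
  }
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  out <- data.frame(
    model = names(fits),
    n_par = vapply(fits, `[[`, numeric(1), "n_par"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    AIC = aic,
    dAIC = aic - min(aic),
    weight = aic_weights(aic),
    row.names = NULL
  )
  attr(out, "selected") <- out$model[which.min(out$AIC)]
  class(out) <- c("mk_model_comparison", "data.frame")
  out
}

#' Pagel's lambda branch-length transformation
#'
#' Internal edges are multiplied by `lambda`; each terminal edge is then
#' lengthened so every root-to-tip depth equals its original value.
#' `lambda = 1` is the identity; `lambda = 0` collapses all internal
#' structure (a star-like tree with the original depths).
#'
#' @param tree An ultrametric `phylo`.
#' @param lambda Value in \[0, 1\].
#' @return Transformed `phylo`.
#' @export
lambda_transform <- function(tree, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (!is_ultrametric(tree, 1e-6)) stop("tree must be ultrametric")
  if (lambda == 1) return(tree)
  ntip <- ape::Ntip(tree)
  depths <- node_depths(tree)
  out <- tree
  is_tip_edge <- tree$edge[, 2] <= ntip
  out$edge.length[!is_tip_edge] <- lambda * tree$edge.length[!is_tip_edge]
  ## tip edge grows by (1 - lambda) * parent depth, preserving total depth
  par_depth <- depths[tree$edge[is_tip_edge, 1]]
  out$edge.length[is_tip_edge] <- tree$edge.length[is_tip_edge] +
    (1 - lambda) * par_depth
  out
}

#' Phylogenetic signal of a binary character (discrete Pagel's lambda)
#'
#' Joint maximum likelihood over `lambda` in \[0, 1\] and the rate(s) of an
#' Mk model evaluated on the lambda-transformed tree; significance by a
#' likelihood-ratio test of `lambda_hat` against `lambda = 0` (star-like
#' tree). The chi-square(1) reference is the default; because `lambda = 0`
#' lies on the boundary a 50:50 mixture reference is available.
#'
#' @inheritParams fit_mk
#' @param model Rate constraint used for the Mk likelihood (default ER).
#' @param p_reference `"chisq1"` or `"mixture"` (50:50 point mass at 0 and
#'   chi-square(1)).
#' @return Class `"lambda_fit"`: list with `lambda`, `rates`, `loglik`,
#'   `loglik0`, `LR`, `p_value`.
#' @export
fit_lambda <- function(tree, states, model = "ER", pi = "equal",
                       p_reference = c("chisq1", "mixture"), seed = 1L) {
  p_reference <- match.arg(p_reference)
  tm <- mk_tip_matrix(tree, states)
  if (length(tm$labels) != 2L) stop("binary states required (found ",
                                    length(tm$labels), ")")
  np <- mk_n_rates(model, 2)
  nll_at <- function(lambda, logr) {
    tr <- lambda_transform(tree, lambda)
    Q <- mk_q_matrix(exp(logr), model, 2, tm$labels)
    piv <- root_prior_vector(pi, Q, 2)
    -mk_prune(tr, tm$L, Q, piv)$loglik
  }
  total_len <- sum(tree$edge.length)
  start <- rep(log(2 / total_len * ape::Ntip(tree) / 10), np)
  obj <- function(par) {
    v <- nll_at(par[1], par[-1])
    if (!is.finite(v)) 1e10 else v
  }
  best <- NULL
  for (lam0 in c(0.99, 0.5, 0.1)) {
    fit <- try(stats::optim(c(lam0, start), obj, method = "L-BFGS-B",
                            lower = c(0, rep(log(1e-9), np)),
                            upper = c(1, rep(log(1e6), np)),
                            control = list(factr = 1e4)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value - 1e-9) best <- fit
  }
  if (is.null(best)) stop("lambda optimisation failed")
  ## profile fit at lambda = 0 (star-like tree)
  fit0 <- stats::optim(start, function(lr) {
    v <- nll_at(0, lr)
    if (!is.finite(v)) 1e10 else v
  }, method = "L-BFGS-B", lower = rep(log(1e-9), np),
  upper = rep(log(1e6), np), control = list(factr = 1e4))
  ll_hat <- -best$value
  ll0 <- -fit0$value
  if (ll_hat < ll0) {  # boundary solution: lambda_hat = 0
    best$par <- c(0, fit0$par)
    ll_hat <- ll0
  }
  LR <- 2 * (ll_hat - ll0)
  p <- stats::pchisq(LR, df = 1, lower.tail = FALSE)
  if (p_reference == "mixture") p <- if (LR <= 0) 1 else p / 2
  structure(list(
    lambda = unname(best$par[1]), rates = unname(exp(best$par[-1])),
    model = model, loglik = ll_hat, loglik0 = ll0, LR = LR, p_value = p,
    states = tm$labels
  ), class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat("Discrete Pagel's lambda\n")
  cat("  lambda =", format(x$lambda, digits = 4),
      " logL =", format(x$loglik),
      " logL(0) =", format(x$loglik0), "\n")
  cat("  LRT p =", format.pval(x$p_value), "\n")
  invisible(x)
}
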