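## Robustness procedures: family-weighted taxonomic downsampling and
## tree-topology uncertainty, each feeding the stochastic-mapping pipeline.

#' Family sampling fractions
#'
#' For each family in the dataset, the number of sampled species divided by
#' the number of species known to exist in the family. Fractions near 1
#' mark overrepresented families.
#'
#' @param dataset Data frame with columns `species` and `family` (one row
#'   per species).
#' @param richness Named numeric vector (or two-column data frame
#'   `family`, `known`) of known species counts per family.
#' @return Data frame: `family`, `sampled`, `known`, `fraction`.
#' @export
family_fractions <- function(dataset, richness) {
  if (is.data.frame(richness)) {
    richness <- stats::setNames(richness$known, richness$family)
  }
  fams <- table(dataset$family)
  missing <- setdiff(names(fams), names(richness))
  if (length(missing)) {
    stop("no richness for families: ", paste(missing, collapse = ", "))
  }
  known <- richness[names(fams)]
  if (any(known <= 0)) {
    stop("known species count must be positive for: ",
         paste(names(fams)[known <= 0], collapse = ", "))
  }
  data.frame(family = names(fams), sampled = as.integer(fams),
             known = as.numeric(known),
             fraction = as.integer(fams) / as.numeric(known),
             row.names = NULL)
}

#' Family-weighted downsampling of a species set
#'
#' Retains exactly `round(target * N)` species; species are removed
#' sequentially without replacement with probability proportional to their
#' family's sampling fraction, so overrepresented families are removed
#' preferentially.
#'
#' @param dataset Data frame with `species` and `family` columns.
#' @param fractions Output of [family_fractions()].
#' @param target Retained proportion (e.g. 0.7, 0.8, 0.9).
#' @param seed Optional RNG seed.
#' @return Character vector of retained species names.
#' @export
weighted_downsample <- function(dataset, fractions, target, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dataset)
  n_keep <- round(target * n)
  if (n_keep < 2) stop("target keeps fewer than 2 species")
  if (n_keep >= n) return(as.character(dataset$species))
  w <- fractions$fraction[match(dataset$family, fractions$family)]
  if (anyNA(w)) stop("dataset contains families absent from `fractions`")
  drop_idx <- sample.int(n, n - n_keep, replace = FALSE, prob = w)
  as.character(dataset$species[-drop_idx])
}

## combine per-subset summaries (possibly over different pruned trees) by
## pooling their per-map statistics; node posteriors other than the root do
## not pool across tip sets and are dropped
pool_summaries <- function(summaries) {
  labels <- summaries[[1]]$labels
  present <- summaries[[1]]$present_state
  n_maps <- sum(vapply(summaries, `[[`, numeric(1), "n_maps"))
  changes <- unlist(lapply(summaries, `[[`, "changes"))
  gains <- unlist(lapply(summaries, `[[`, "gains"))
  losses <- unlist(lapply(summaries, `[[`, "losses"))
  w <- vapply(summaries, `[[`, numeric(1), "n_maps") / n_maps
  tp <- Reduce(`+`, Map(function(s, wi) s$time_proportions * wi,
                        summaries, w))
  ## pooled root posterior = map-weighted mean of per-subset root posteriors
  root_post <- Reduce(`+`, Map(function(s, wi) {
    rp <- stats::setNames(numeric(length(labels)), labels)
    rp[s$root_state] <- s$root_confidence
    rp[setdiff(labels, s$root_state)] <- 1 - s$root_confidence
    rp * wi
  }, summaries, w))
  root_state <- labels[which.max(root_post)]
  structure(list(
    n_maps = n_maps,
    mean_changes = mean(changes), mean_gains = mean(gains),
    mean_losses = mean(losses),
    changes = changes, gains = gains, losses = losses,
    time_proportions = tp,
    node_posteriors = NULL,
    root_state = root_state,
    root_confidence = unname(root_post[root_state]),
    present_state = present, labels = labels,
    total_tree_time = summaries[[1]]$total_tree_time
  ), class = "simmap_summary")
}

sensitivity_row <- function(label, summary) {
  data.frame(
    analysis = label,
    mean_changes = summary$mean_changes,
    mean_gains = summary$mean_gains,
    mean_losses = summary$mean_losses,
    time_absent = unname(summary$time_proportions[
      setdiff(summary$labels, summary$present_state)[1]]),
    ancestral_state = summary$root_state,
    root_confidence = summary$root_confidence,
    stringsAsFactors = FALSE
  )
}

#' Downsampling sensitivity analysis
#'
#' For each retention target, repeatedly draws a family-weighted subsample,
#' prunes the tree, refits the Mk model (or reuses a fixed Q) and generates
#' stochastic maps; summaries are pooled over all maps per target.
#'
#' @inheritParams run_simmap
#' @param dataset Data frame with `species` and `family` (used for
#'   weighting); `states` must be named by the same species.
#' @param fractions Output of [family_fractions()].
#' @param targets Retained proportions.
#' @param n_subsets Distinct subsamples per target.
#' @param maps_per_subset Stochastic maps per subsample (total maps per
#'   target = `n_subsets * maps_per_subset`).
#' @param refit_q Refit Q on each subsample (default) or fix it at the
#'   full-data estimate (fast mode).
#' @return Data frame, one row per target, with mean changes, gains,
#'   losses, time-absent proportion, ancestral state and root confidence;
#'   per-target `"simmap_summary"` objects in attribute `summaries`.
#' @export
downsample_analysis <- function(tree, states, dataset, fractions,
                                model = "ER", targets = c(0.9, 0.8, 0.7),
                                n_subsets = 100, maps_per_subset = 100,
                                seed = 1L, refit_q = TRUE, pi = "equal",
                                present_state = NULL) {
  full_fit <- fit_mk(tree, states, model = model, pi = pi)
  set.seed(seed)
  rows <- list(); summaries <- list()
  for (tg in targets) {
    subset_summaries <- vector("list", n_subsets)
    for (r in seq_len(n_subsets)) {
      keep <- weighted_downsample(dataset, fractions, tg)
      sub_tree <- prune_to_taxa(tree, keep)
      sub_states <- states[keep]
      Qr <- if (refit_q) NULL else full_fit$Q
      maps_r <- run_simmap(sub_tree, sub_states, model = model,
                           nsim = maps_per_subset,
                           seed = sample.int(.Machine$integer.max, 1),
                           Q = Qr, pi = pi)
      subset_summaries[[r]] <- summarize_maps(maps_r,
                                              present_state = present_state)
    }
    sm <- pool_summaries(subset_summaries)
    lab <- sprintf("subset %d%%", round(tg * 100))
    rows[[lab]] <- sensitivity_row(lab, sm)
    summaries[[lab]] <- sm
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "summaries") <- summaries
  out
}

#' Tree-topology uncertainty analysis
#'
#' Randomly samples trees from a posterior (or pseudo-posterior) set,
#' refits the rate matrix on each, draws `maps_per_tree` stochastic maps
#' per tree, and pools all maps into one summary.
#'
#' @inheritParams run_simmap
#' @param trees A `multiPhylo` sharing the data's tip set.
#' @param n_trees Trees to sample from the set.
#' @param maps_per_tree Maps per sampled tree.
#' @return One-row data frame as in [downsample_analysis()], with the
#'   pooled `"simmap_summary"` in attribute `summary` and per-tree root
#'   confidences in attribute `per_tree_confidence`.
#' @export
tree_uncertainty_analysis <- function(trees, states, model = "ER",
                                      n_trees = 100, maps_per_tree = 100,
                                      seed = 1L, pi = "equal",
                                      present_state = NULL) {
  if (length(trees) < n_trees) {
    stop("tree set has ", length(trees), " trees; need ", n_trees)
  }
  tipset <- sort(trees[[1]]$tip.label)
  if (!setequal(tipset, names(states))) {
    stop("tip set of trees does not match names of `states`")
  }
  set.seed(seed)
  pick <- sample.int(length(trees), n_trees)
  sets <- vector("list", n_trees)
  for (i in seq_along(pick)) {
    tr <- trees[[pick[i]]]
    sets[[i]] <- run_simmap(tr, states, model = model, nsim = maps_per_tree,
                            seed = sample.int(.Machine$integer.max, 1),
                            pi = pi)
  }
  sm <- summarize_maps(sets, present_state = present_state)
  per_tree <- vapply(sets, function(s) {
    ss <- summarize_maps(s, present_state = present_state)
    ss$node_posteriors[ape::Ntip(s$tree) + 1L, sm$root_state]
  }, numeric(1))
  out <- sensitivity_row("random trees", sm)
  attr(out, "summary") <- sm
  attr(out, "per_tree_confidence") <- per_tree
  out
}
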