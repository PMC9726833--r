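## Pipeline orchestrators: each runs one stage of the analysis end to end
## (tree repair -> model selection -> mapping -> summaries), optionally
## writing its artifact bundle (CSV/JSON/Newick + a reproducibility
## manifest) to an output directory.

prepare_tree <- function(tree, floor = 1e-6) {
  tree <- fix_negative_edges(tree, floor)
  force_ultrametric(tree)
}

write_manifest <- function(outdir, config) {
  manifest <- c(list(package = "bristlephy",
                     version = as.character(utils::packageVersion("bristlephy")),
                     timestamp = format(Sys.time(), tz = "UTC")), config)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Ancestral-state reconstruction pipeline
#'
#' Repairs the tree, prunes it to the scored species, fits the candidate
#' Mk models, selects by AIC, generates stochastic maps under the selected
#' model and summarises them, including a density map.
#'
#' @param tree A `phylo` (repaired and coerced ultrametric internally).
#' @param states Named binary state vector (species -> state label).
#' @param models Candidate constraint models.
#' @param nsim Number of stochastic maps.
#' @param seed Master seed.
#' @param outdir Optional output directory for the artifact bundle
#'   (comparison CSV, summary JSON, density Newick, segment CSV, manifest).
#' @param present_state State counted as "present".
#' @param density_bins Bins per edge for the density map.
#' @return List: `tree`, `comparison`, `selected`, `fits`, `maps`
#'   (`"simmap_maps"`), `summary`, `density`.
#' @export
run_asr <- function(tree, states, models = c("ER", "SYM", "ARD"),
                    nsim = 10000, seed = 1L, outdir = NULL,
                    present_state = NULL, density_bins = 100) {
  tree <- prepare_tree(tree)
  common <- intersect(tree$tip.label, names(states))
  if (length(common) < length(tree$tip.label)) {
    tree <- prune_to_taxa(tree, common)
  }
  states <- states[tree$tip.label]
  fits <- lapply(models, function(m) fit_mk(tree, states, model = m, seed = seed))
  names(fits) <- models
  comp <- compare_models(fits)
  selected <- attr(comp, "selected")
  maps <- run_simmap(tree, states, Q = fits[[selected]]$Q, nsim = nsim,
                     seed = seed)
  summ <- summarize_maps(maps, present_state = present_state)
  dens <- density_map(maps, bins = density_bins,
                      present_state = present_state)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(comp, file.path(outdir, "model_comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(n_maps = summ$n_maps, mean_changes = summ$mean_changes,
           mean_gains = summ$mean_gains, mean_losses = summ$mean_losses,
           time_proportions = as.list(summ$time_proportions),
           root_state = summ$root_state,
           root_confidence = summ$root_confidence),
      file.path(outdir, "map_summary.json"), auto_unbox = TRUE, digits = NA)
    write_density_newick(dens, file.path(outdir, "density_map.nwk"))
    utils::write.csv(map_segments(maps), file.path(outdir, "map_segments.csv"),
                     row.names = FALSE)
    write_manifest(outdir, list(stage = "asr", seed = seed, nsim = nsim,
                                models = models, selected = selected,
                                n_species = length(states)))
  }
  list(tree = tree, comparison = comp, selected = selected, fits = fits,
       maps = maps, summary = summ, density = dens)
}

#' Phylogenetic-signal pipeline
#'
#' Fits the discrete Pagel's lambda for each binary character column.
#'
#' @param tree A `phylo`.
#' @param characters Data frame or named list: one named binary vector
#'   (species -> 0/1) per character, or a data frame with species rownames.
#' @param seed Seed (restarts).
#' @param outdir Optional output directory (`phylo_signal.csv` + manifest).
#' @return Data frame: character, lambda, loglik, loglik0, LR, p_value.
#' @export
run_signal <- function(tree, characters, seed = 1L, outdir = NULL) {
  tree <- prepare_tree(tree)
  if (is.data.frame(characters)) {
    characters <- lapply(characters, function(col)
      stats::setNames(as.character(col), rownames(characters)))
  }
  rows <- lapply(names(characters), function(ch) {
    st <- characters[[ch]][tree$tip.label]
    fit <- fit_lambda(tree, st, seed = seed)
    data.frame(character = ch, lambda = fit$lambda, loglik = fit$loglik,
               loglik0 = fit$loglik0, LR = fit$LR, p_value = fit$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(outdir, "phylo_signal.csv"),
                     row.names = FALSE)
    write_manifest(outdir, list(stage = "signal", seed = seed,
                                characters = names(characters)))
  }
  out
}

#' Sensitivity pipeline (downsampling + tree uncertainty)
#'
#' @inheritParams downsample_analysis
#' @param trees Optional `multiPhylo` posterior/pseudo-posterior set for
#'   the topology-uncertainty row.
#' @param outdir Optional output directory (`sensitivity.csv` + manifest).
#' @return Data frame shaped like the sensitivity table: one row per
#'   analysis (random trees first when `trees` is given, then each subset).
#' @export
run_sensitivity_pipeline <- function(tree, states, dataset, fractions,
                                     trees = NULL, model = "ER",
                                     targets = c(0.9, 0.8, 0.7),
                                     n_subsets = 100, maps_per_subset = 100,
                                     n_trees = 100, maps_per_tree = 100,
                                     seed = 1L, outdir = NULL,
                                     present_state = NULL) {
  tree <- prepare_tree(tree)
  rows <- list()
  if (!is.null(trees)) {
    rows$trees <- tree_uncertainty_analysis(trees, states, model = model,
                                            n_trees = n_trees,
                                            maps_per_tree = maps_per_tree,
                                            seed = seed,
                                            present_state = present_state)
    attr(rows$trees, "summary") <- NULL
  }
  ds <- downsample_analysis(tree, states, dataset, fractions, model = model,
                            targets = targets, n_subsets = n_subsets,
                            maps_per_subset = maps_per_subset, seed = seed,
                            present_state = present_state)
  attr(ds, "summaries") <- NULL
  out <- rbind(do.call(rbind, rows), ds)
  rownames(out) <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(outdir, "sensitivity.csv"),
                     row.names = FALSE)
    write_manifest(outdir, list(stage = "sensitivity", seed = seed,
                                targets = targets, n_subsets = n_subsets,
                                maps_per_subset = maps_per_subset))
  }
  out
}

#' Ecological-association pipeline (phylogenetic mixed model)
#'
#' @inheritParams run_pglmm
#' @param eliminate Run [backward_eliminate()] after the full fit.
#' @param outdir Optional output directory (`model_summary.json`,
#'   `caterpillar.csv`, per-chain CSVs, manifest).
#' @return List: `fit`, `summary`, `caterpillar`, and (when `eliminate`)
#'   `elimination`.
#' @export
run_glmm <- function(data, tree, spec, prior = pglmm_prior(), seed = 1L,
                     eliminate = FALSE, outdir = NULL, jitter = 0) {
  tree <- prepare_tree(tree)
  fit <- run_pglmm(data, tree, spec, prior, seed = seed, jitter = jitter)
  summ <- summarize_model(fit)
  cat_tab <- caterpillar_table(summ)
  elim <- if (eliminate) {
    backward_eliminate(data, tree, spec, prior, seed = seed, jitter = jitter)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(table = summ$table, DIC = summ$DIC, converged = summ$converged),
      file.path(outdir, "model_summary.json"), auto_unbox = TRUE,
      digits = NA)
    utils::write.csv(cat_tab, file.path(outdir, "caterpillar.csv"),
                     row.names = FALSE)
    for (i in seq_along(fit$chains)) {
      utils::write.csv(as.data.frame(as.matrix(fit$chains[[i]])),
                       file.path(outdir, sprintf("chain_%d.csv", i)),
                       row.names = FALSE)
    }
    write_manifest(outdir, list(stage = "glmm", seed = seed,
                                response = spec$response,
                                family = spec$family, fixed = spec$fixed,
                                plan = spec$plan, chains = spec$chains))
  }
  out <- list(fit = fit, summary = summ, caterpillar = cat_tab)
  if (eliminate) out$elimination <- elim
  out
}
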