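#' Parse phylogenies from Newick or Nexus text
#'
#' Reads one or more trees from a character string or a file, in either
#' Newick or Nexus dialect (auto-detected from the `#NEXUS` header unless
#' `format` is given). Tip labels are normalised to a canonical form in
#' which internal spaces become underscores, so quoted names
#' (`'Gallus gallus'`) and underscore names (`Gallus_gallus`) refer to the
#' same taxon.
#'
#' @param text Character scalar holding the tree text. Exactly one of
#'   `text`/`file` must be supplied.
#' @param file Path to a tree file.
#' @param format One of `"auto"`, `"newick"`, `"nexus"`.
#' @param provenance Label stored on the returned set, e.g.
#'   `"posterior sample"` or `"synthetic"`.
#' @return A `multiPhylo` object (even for a single tree) with a
#'   `"provenance"` attribute. Use [parse_tree()] for a single `phylo`.
#' @export
parse_trees <- function(text = NULL, file = NULL,
                        format = c("auto", "newick", "nexus"),
                        provenance = "unspecified") {
  format <- match.arg(format)
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `text` or `file`")
  }
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  if (format == "auto") {
    format <- if (grepl("^\\s*#NEXUS", text, ignore.case = TRUE)) "nexus" else "newick"
  }
  trees <- tryCatch(
    {
      if (format == "nexus") {
        tf <- tempfile(fileext = ".nex")
        on.exit(unlink(tf), add = TRUE)
        writeLines(text, tf)
        ape::read.nexus(tf)
      } else {
        ape::read.tree(text = text)
      }
    },
    error = function(e) stop("tree parse error (", format, "): ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(trees)) stop("tree parse error (", format, "): no tree found in input")
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  trees <- structure(lapply(trees, normalize_tip_labels), class = "multiPhylo")
  for (i in seq_along(trees)) validate_phylogeny(trees[[i]])
  tipsets <- lapply(trees, function(tr) sort(tr$tip.label))
  if (length(trees) > 1L && !all(vapply(tipsets, identical, logical(1), tipsets[[1]]))) {
    stop("trees in a set must share an identical tip-label set")
  }
  attr(trees, "provenance") <- provenance
  trees
}

#' @rdname parse_trees
#' @export
parse_tree <- function(text = NULL, file = NULL,
                       format = c("auto", "newick", "nexus")) {
  trees <- parse_trees(text = text, file = file, format = format)
  if (length(trees) != 1L) stop("expected exactly one tree, found ", length(trees))
  trees[[1]]
}

normalize_tip_labels <- function(tree) {
  tree$tip.label <- gsub(" ", "_", gsub("^'|'$", "", tree$tip.label))
  tree
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a `phylo` object")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  invisible(tree)
}

#' Write trees to Newick or Nexus text
#'
#' @param trees A `phylo` or `multiPhylo`.
#' @param file Optional path; when `NULL` the text is returned.
#' @param format `"newick"` (default) or `"nexus"` (a TREES block).
#' @param digits Significant digits for branch lengths (Newick).
#' @return Character vector of tree text (invisibly when writing to file).
#' @export
write_trees <- function(trees, file = NULL, format = c("newick", "nexus"),
                        digits = 12) {
  format <- match.arg(format)
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  if (format == "nexus") {
    tf <- if (is.null(file)) tempfile(fileext = ".nex") else file
    ape::write.nexus(trees, file = tf, translate = FALSE)
    txt <- readLines(tf)
    if (is.null(file)) unlink(tf)
  } else {
    txt <- vapply(trees, function(tr) ape::write.tree(tr, digits = digits),
                  character(1))
    if (!is.null(file)) writeLines(txt, file)
  }
  if (!is.null(file)) return(invisible(txt))
  txt
}

#' Prune a phylogeny to a set of taxa
#'
#' Drops all tips not in `keep`, suppressing the resulting unary nodes so
#' that retained root-to-tip path lengths are unchanged.
#'
#' @param tree A `phylo`.
#' @param keep Character vector of tip labels to retain (>= 2).
#' @return The pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    stop("taxa not present in tree: ", paste(missing, collapse = ", "))
  }
  if (length(keep) < 2L) stop("`keep` must contain at least 2 tips")
  ape::keep.tip(tree, keep)
}

#' Floor negative branch lengths
#'
#' Consensus trees summarising clade ages across a posterior can carry
#' slightly negative branch lengths; strictly negative edges are raised to a
#' small positive floor, all other edges are untouched.
#'
#' @param tree A `phylo`.
#' @param floor Replacement length for negative edges.
#' @return The repaired `phylo`.
#' @export
fix_negative_edges <- function(tree, floor = 1e-6) {
  tree$edge.length[tree$edge.length < 0] <- floor
  tree
}

#' Coerce a tree to ultrametric
#'
#' Default method refits all edge lengths by non-negative least squares
#' against the tree's own patristic distances subject to equal root-to-tip
#' depths (topology unchanged); `method = "extend"` simply lengthens each
#' terminal edge to the maximum depth (fast, but distorts only tip edges).
#'
#' @param tree A `phylo` with non-negative edge lengths.
#' @param method `"nnls"` (least squares, default) or `"extend"`.
#' @param tol Relative tolerance used to declare the result ultrametric.
#' @return An ultrametric `phylo`.
#' @export
force_ultrametric <- function(tree, method = c("nnls", "extend"), tol = 1e-8) {
  method <- match.arg(method)
  if (any(tree$edge.length < 0)) {
    stop("negative edge lengths; run fix_negative_edges() first")
  }
  if (is_ultrametric(tree, tol)) return(tree)
  if (method == "nnls") {
    out <- phangorn::nnls.tree(stats::cophenetic(tree), tree,
                               method = "ultrametric")
    ## numerically-zero negatives from the solver are clamped
    out$edge.length[out$edge.length < 0 & out$edge.length > -1e-8] <- 0
  } else {
    depths <- node_depths(tree)
    h <- max(depths[seq_len(ape::Ntip(tree))])
    out <- tree
    tip_edge <- match(seq_len(ape::Ntip(tree)), tree$edge[, 2])
    out$edge.length[tip_edge] <- out$edge.length[tip_edge] +
      (h - depths[seq_len(ape::Ntip(tree))])
  }
  if (!is_ultrametric(out, sqrt(tol))) {
    d <- node_depths(out)[seq_len(ape::Ntip(out))]
    stop("ultrametric coercion failed; residual depth spread = ",
         format(diff(range(d))))
  }
  out
}

#' Root-to-tip depth of every node
#'
#' @param tree A `phylo`.
#' @return Numeric vector over node ids (tips first), depth from the root.
#' @export
node_depths <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  depths <- numeric(n_node)
  tree <- stats::reorder(tree)  # cladewise: parents before children
  for (i in seq_len(nrow(tree$edge))) {
    depths[tree$edge[i, 2]] <- depths[tree$edge[i, 1]] + tree$edge.length[i]
  }
  depths
}

#' Is a tree ultrametric?
#'
#' @param tree A `phylo`.
#' @param tol Relative tolerance on the spread of root-to-tip depths.
#' @export
is_ultrametric <- function(tree, tol = 1e-8) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  diff(range(d)) <= tol * max(max(d), .Machine$double.eps)
}

#' Root age of an ultrametric tree
#'
#' The common root-to-tip path length (crown age), in the tree's time units.
#'
#' @param tree An ultrametric `phylo`.
#' @param tol Ultrametricity tolerance.
#' @return Numeric scalar.
#' @export
root_age <- function(tree, tol = 1e-6) {
  if (!is_ultrametric(tree, tol)) stop("tree is not ultrametric")
  mean(node_depths(tree)[seq_len(ape::Ntip(tree))])
}

#' Phylogenetic correlation matrix of the tips
#'
#' Entry (i, j) is the shared root-ward path length of tips i and j divided
#' by the root age; the diagonal is 1. This is the correlation structure a
#' Brownian trait accrues on an ultrametric tree, used by the phylogenetic
#' random effect of the mixed models.
#'
#' @param tree An ultrametric `phylo`.
#' @return Symmetric positive semi-definite matrix with unit diagonal,
#'   dimnames = tip labels.
#' @export
phylo_correlation <- function(tree, tol = 1e-6) {
  if (!is_ultrametric(tree, tol)) stop("tree is not ultrametric")
  C <- ape::vcv(tree, corr = TRUE)
  (C + t(C)) / 2
}
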