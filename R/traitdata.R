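## Specimen/species bristle records: derived analysis variables, species
## aggregation, guild-combination coding, and the sex-pooling tests.

#' Ecological trait vocabularies
#'
#' The controlled vocabularies for the five ecological traits (activity
#' period, habitat type, diet, foraging method, foraging height), shipped
#' as a versioned JSON resource under `extdata`.
#'
#' @return Named list of character vectors.
#' @export
ecology_vocab <- function() {
  path <- system.file("extdata", "ecology_vocab.json", package = "bristlephy")
  if (path == "") path <- file.path("inst", "extdata", "ecology_vocab.json")
  jsonlite::fromJSON(path)
}

#' Bristle shape categories
#' @return Character vector: Absent, Base, Branched, Unbranched.
#' @export
shape_categories <- function() c("Absent", "Base", "Branched", "Unbranched")

#' Derive rictal-bristle presence
#'
#' "Rictal bristle" covers bristles on the upper rictal and/or lorial
#' region; presence is the logical OR of the two regional flags.
#'
#' @param upper,lorial Logical flags (vectorised).
#' @export
derive_rictal_presence <- function(upper, lorial) {
  as.logical(upper) | as.logical(lorial)
}

#' Mean rictal-bristle length of a specimen
#'
#' The three longest bristles are measured on each side of the head; the
#' specimen's length is the arithmetic mean over all available
#' measurements (a missing side contributes nothing). Specimens without
#' rictal bristles carry length 0 and shape "Absent".
#'
#' @param left,right Numeric vectors of up to 3 lengths (mm) each.
#' @return Mean length in mm; 0 when no measurements are provided.
#' @export
specimen_mean_length <- function(left = numeric(0), right = numeric(0)) {
  vals <- c(left, right)
  vals <- vals[!is.na(vals)]
  if (any(vals < 0)) stop("bristle lengths must be non-negative")
  if (length(vals) > 6) stop("at most 3 measurements per side")
  if (!length(vals)) return(0)
  mean(vals)
}

#' Aggregate specimen records to species-level traits
#'
#' Presence per region is the OR over specimens (a species counts as having
#' bristles if any specimen does); species length is the mean of specimen
#' mean lengths; shape is the modal non-Absent category, ties broken by
#' precedence Unbranched > Branched > Base.
#'
#' @param records Data frame of specimens of ONE species with columns
#'   `species`, presence flags (`upper_rictal`, `lorial`, `lower_rictal`,
#'   `narial`, `interramal`), `mean_length` (per specimen, mm), `shape`,
#'   and optionally `family` and ecological columns (taken from the first
#'   specimen).
#' @return One-row data frame of species traits with derived `rictal`
#'   presence.
#' @export
species_aggregate <- function(records) {
  if (!nrow(records)) stop("no specimen records supplied")
  sp <- unique(records$species)
  if (length(sp) != 1L) stop("records must belong to one species, found: ",
                             paste(sp, collapse = ", "))
  pres <- function(col) any(as.logical(records[[col]]))
  rictal <- any(derive_rictal_presence(records$upper_rictal, records$lorial))
  mean_len <- mean(records$mean_length)
  shapes <- setdiff(records$shape, "Absent")
  shape <- if (!rictal || !length(shapes)) "Absent" else {
    tab <- table(shapes)
    cands <- names(tab)[tab == max(tab)]
    prec <- c("Unbranched", "Branched", "Base")
    prec[prec %in% cands][1]
  }
  out <- data.frame(
    species = sp,
    rictal = rictal,
    lower_rictal = pres("lower_rictal"),
    narial = pres("narial"),
    interramal = pres("interramal"),
    mean_length = if (rictal) mean_len else 0,
    shape = shape,
    n_specimens = nrow(records),
    stringsAsFactors = FALSE
  )
  for (col in intersect(c("family", "activity", "habitat", "diet",
                          "foraging_method", "foraging_height"),
                        names(records))) {
    out[[col]] <- records[[col]][1]
  }
  out
}

#' Aggregate a whole specimen table to species level
#'
#' @param specimens Specimen table (see [species_aggregate()]).
#' @return Species-level data frame, one row per species.
#' @export
aggregate_species_table <- function(specimens) {
  parts <- lapply(split(specimens, specimens$species), species_aggregate)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Combine up to two guilds into a category label
#'
#' Species spanning two dietary guilds (or two foraging methods) are coded
#' as `"Primary-Secondary"` with an en dash, primary first; a single guild
#' is its own label.
#'
#' @param primary Main guild.
#' @param secondary Secondary guild or `NA`/`NULL`.
#' @param vocabulary Allowed guild names (checked when supplied).
#' @return Character label.
#' @export
combine_guilds <- function(primary, secondary = NULL, vocabulary = NULL) {
  if (length(primary) != 1L) stop("at most two guilds may be combined")
  if (!is.null(secondary) && length(secondary) > 1L) {
    stop("at most two guilds may be combined")
  }
  if (!is.null(vocabulary)) {
    bad <- setdiff(stats::na.omit(c(primary, unlist(secondary))), vocabulary)
    if (length(bad)) stop("unknown guild(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(secondary) || is.na(secondary)) return(primary)
  paste(primary, secondary, sep = "–")
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' W is the rank sum of `x` (mid-ranks for ties) minus `n_x(n_x+1)/2`; the
#' p-value uses the normal approximation with tie-corrected variance and
#' continuity correction, two-sided. With zero rank variance (all values
#' identical across both samples) the test is degenerate and reported with
#' `p = 1` and a flag.
#'
#' @param x,y Numeric samples.
#' @return List of class `"bristle_test"`: `statistic_name`, `statistic`,
#'   `N`, `p_value`, `degenerate`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  pooled <- c(x, y)
  degenerate <- length(unique(pooled)) == 1L
  if (degenerate) {
    W <- length(x) * length(y) / 2
    p <- 1
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    )
    W <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(list(statistic_name = "MannWhitneyW", statistic = W,
                 N = length(pooled), df = NA_real_, p_value = p,
                 degenerate = degenerate), class = "bristle_test")
}

#' Pearson chi-square test on a contingency table
#'
#' @param tab An r x c matrix of non-negative counts.
#' @param N Sample size to report (defaults to the grand total).
#' @return List of class `"bristle_test"` with the Pearson statistic,
#'   `df = (r-1)(c-1)` and the upper-tail p-value.
#' @export
chi_square <- function(tab, N = sum(tab)) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (sum(tab) <= 0) stop("table has no observations")
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    stop("degenerate margin: ",
         paste(c(if (any(zr)) paste("row", which(zr)),
                 if (any(zc)) paste("column", which(zc))), collapse = ", "))
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("degenerate margin: table must be at least 2 x 2 (df would be 0)")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(statistic_name = "ChiSquare",
                 statistic = unname(ht$statistic), N = N,
                 df = unname(ht$parameter), p_value = ht$p.value,
                 degenerate = FALSE), class = "bristle_test")
}

#' @export
print.bristle_test <- function(x, ...) {
  cat(x$statistic_name, "=", format(x$statistic),
      if (!is.na(x$df)) paste(", df =", x$df) else "",
      ", N =", x$N, ", p =", format.pval(x$p_value), "\n")
  invisible(x)
}

#' Presence/shape partition check
#'
#' Species either lack rictal bristles (shape Absent) or carry one of the
#' three shape categories; the counts must partition the species total.
#'
#' @param species_table Species-level table from [aggregate_species_table()].
#' @return Named integer vector of counts per shape category with attribute
#'   `total`.
#' @export
shape_counts <- function(species_table) {
  counts <- table(factor(species_table$shape, levels = shape_categories()))
  out <- as.integer(counts)
  names(out) <- shape_categories()
  attr(out, "total") <- nrow(species_table)
  out
}
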