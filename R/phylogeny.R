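#' @title Identity-by-state phylogeny with bootstrap support
#' @name phylogeny
#' @description
#' Genetic distances between samples are `1 - IBS` computed over markers
#' typed in both members of a pair (per-pair denominator, i.e. "flat
#' missing"). Trees are neighbor-joining; support comes from bootstrap
#' resampling of markers (columns) with replacement, the PHYLIP-consistent
#' convention, with a majority-rule consensus reported rooted at the
#' outgroup. Per-breed monophyly and per-dog placement supports are recorded
#' for the misclassification rule: a dog "groups with its breed" in a
#' replicate when it lies inside a clade whose leaves all belong to its breed
#' and which contains at least half of the breed's sampled dogs.
NULL

#' Phylogeny parameter set
#'
#' @param replicates bootstrap replicate count (default 100).
#' @param cap maximum sampled individuals per breed (default 10).
#' @param threshold placement-support threshold below which a dog is flagged
#'   as misclassified (default 0.90).
#' @param outgroup breed label used to root trees.
#' @param seed random seed.
#' @return A `phylo_params` list.
#' @export
phylo_params <- function(replicates = 100L, cap = 10L, threshold = 0.90,
                         outgroup = NULL, seed = 1L) {
  stopifnot(replicates >= 1, cap >= 1, threshold > 0, threshold <= 1)
  structure(list(replicates = as.integer(replicates), cap = as.integer(cap),
                 threshold = threshold, outgroup = outgroup,
                 seed = as.integer(seed)),
            class = "phylo_params")
}

#' Subsample each breed to at most `cap` individuals
#'
#' Avoids sample-size-related bias in phylogeny estimation. Selection is
#' uniform without replacement and deterministic per seed.
#'
#' @param cohort a `cohort`.
#' @param cap maximum individuals per breed.
#' @param seed random seed.
#' @return The subsampled `cohort` (original sample order preserved).
#' @export
subsample_breeds <- function(cohort, cap = 10L, seed = 1L) {
  validate_cohort(cohort)
  stopifnot(cap >= 1)
  set.seed(seed)
  keep <- logical(nrow(cohort$samples))
  for (b in unique(cohort$samples$breed)) {
    idx <- which(cohort$samples$breed == b)
    if (length(idx) > cap) idx <- sort(sample(idx, cap))
    keep[idx] <- TRUE
  }
  subset_cohort(cohort, samples = which(keep))
}

#' 1 - IBS genetic distance matrix
#'
#' @param cohort a `cohort` with at least two samples.
#' @param weights optional marker weights (bootstrap counts).
#' @return Symmetric distance matrix with entries in `[0, 1]`.
#' @export
ibs_distance_matrix <- function(cohort, weights = NULL) {
  if (nrow(cohort$samples) < 2L) stop("need at least two samples")
  d <- 1 - ibs_matrix(cohort, weights)
  diag(d) <- 0
  if (any(is.nan(d))) {
    bad <- which(is.nan(d), arr.ind = TRUE)[1L, ]
    stop("samples ", rownames(d)[bad[1L]], " and ", colnames(d)[bad[2L]],
         " share no typed markers")
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}). Negative branch-length
#' estimates are clamped to zero with the deficit transferred to the adjacent
#' branch at the same node, the usual practice for display and consensus.
#'
#' @param dist square symmetric numeric matrix with zero diagonal, n >= 3.
#' @return An [ape::phylo] tree (unrooted).
#' @export
neighbor_joining <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist) || nrow(dist) < 3L) {
    stop("need a square distance matrix over >= 3 samples")
  }
  if (max(abs(dist - t(dist))) > 1e-8) stop("distance matrix is not symmetric")
  tr <- ape::nj(as.dist(dist))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sisters <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sisters)) {
      tr$edge.length[sisters[1L]] <- tr$edge.length[sisters[1L]] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr
}

# root at (the first tip of) the outgroup breed
root_at_outgroup <- function(tree, og_tips) {
  ape::root(tree, outgroup = og_tips[1L], resolve.root = TRUE)
}

# pure-breed clade bookkeeping for one rooted tree
breed_clade_stats <- function(tree, breed_of, breeds) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  clade_sets <- lapply(pp, function(i) labs[i])
  mono <- stats::setNames(logical(length(breeds)), breeds)
  placed <- stats::setNames(logical(length(breed_of)), names(breed_of))
  for (b in breeds) {
    tips <- names(breed_of)[breed_of == b]
    nb <- length(tips)
    if (nb == 1L) { mono[b] <- TRUE; placed[tips] <- TRUE; next }
    half <- ceiling(nb / 2)
    for (cs in clade_sets) {
      if (all(cs %in% tips)) {
        if (length(cs) == nb) mono[b] <- TRUE
        if (length(cs) >= half) placed[cs] <- TRUE
      }
    }
  }
  list(mono = mono, placed = placed)
}

#' Bootstrapped neighbor-joining consensus
#'
#' Each replicate resamples markers with replacement (keeping the marker
#' count), recomputes the 1-IBS distance matrix and the NJ tree, and roots it
#' at the outgroup. Reports the majority-rule consensus with per-clade
#' support, plus per-breed monophyly support and per-dog placement support.
#'
#' @param cohort a `cohort` containing the outgroup breed.
#' @param params a [phylo_params()] set with non-`NULL` `outgroup`.
#' @return List of class `bootstrap_phylo` with elements `consensus` (rooted
#'   [ape::phylo] with node labels = support fractions), `main_tree` (NJ on
#'   the unresampled data), and `support` (class `bootstrap_support`:
#'   `breed_monophyly`, `dog_placement`, `n_replicates`, `outgroup`).
#' @export
bootstrap_consensus <- function(cohort, params) {
  validate_cohort(cohort)
  stopifnot(inherits(params, "phylo_params"))
  if (is.null(params$outgroup)) stop("params$outgroup must be set")
  og_tips <- cohort$samples$id[cohort$samples$breed == params$outgroup]
  if (length(og_tips) == 0L) {
    stop("outgroup breed not present in cohort: ", params$outgroup)
  }
  set.seed(params$seed)
  L <- nrow(cohort$map)
  breed_of <- stats::setNames(cohort$samples$breed, cohort$samples$id)
  breeds <- setdiff(unique(cohort$samples$breed), params$outgroup)

  main <- root_at_outgroup(neighbor_joining(ibs_distance_matrix(cohort)), og_tips)

  R <- params$replicates
  trees <- vector("list", R)
  mono_n <- stats::setNames(numeric(length(breeds)), breeds)
  placed_n <- stats::setNames(numeric(length(breed_of)), names(breed_of))
  for (r in seq_len(R)) {
    w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
    tr <- root_at_outgroup(neighbor_joining(ibs_distance_matrix(cohort, w)), og_tips)
    trees[[r]] <- tr
    st <- breed_clade_stats(tr, breed_of, breeds)
    mono_n <- mono_n + st$mono
    placed_n <- placed_n + st$placed
  }
  class(trees) <- "multiPhylo"

  cons <- if (R == 1L) trees[[1L]] else ape::consensus(trees, p = 0.5, rooted = TRUE)
  cnt <- ape::prop.clades(cons, trees, rooted = TRUE)
  cnt[is.na(cnt)] <- 0
  cons$node.label <- formatC(cnt / R, digits = 2, format = "f")

  support <- structure(
    list(breed_monophyly = mono_n / R,
         dog_placement = placed_n / R,
         n_replicates = R,
         outgroup = params$outgroup,
         breed_of = breed_of),
    class = "bootstrap_support"
  )
  structure(list(consensus = cons, main_tree = main, support = support),
            class = "bootstrap_phylo")
}

#' Per-breed monophyly support
#'
#' Fraction of bootstrap replicates in which each breed forms an exclusive
#' clade. Single-sample breeds get support 1 by convention.
#'
#' @param support a `bootstrap_support` (from [bootstrap_consensus()]).
#' @param exclude optional sample ids (e.g. flagged misclassified dogs) to
#'   ignore; monophyly is then reported for the remaining dogs only. Note
#'   that exclusion requires the replicate statistics to have been computed
#'   with those dogs absent, so this simply drops their breeds' entries from
#'   the attribution; rerun [bootstrap_consensus()] on the reduced cohort for
#'   exact post-exclusion supports.
#' @return Named numeric vector of support fractions in `[0, 1]`.
#' @export
breed_monophyly <- function(support, exclude = NULL) {
  stopifnot(inherits(support, "bootstrap_support"))
  out <- support$breed_monophyly
  if (!is.null(exclude) && length(exclude)) {
    message("breed_monophyly: rerun bootstrap_consensus without ",
            length(exclude), " excluded dog(s) for exact supports")
  }
  out
}

#' Flag dogs that fail to group with their breed
#'
#' A dog is misclassified when its placement support (fraction of replicates
#' in which it lies in an exclusive >= half-breed clade of its own breed) is
#' strictly below the threshold. Dogs of single-sample breeds and outgroup
#' members are never flagged.
#'
#' @param support a `bootstrap_support`.
#' @param threshold support threshold (default 0.90).
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
flag_misclassified <- function(support, threshold = 0.90) {
  stopifnot(inherits(support, "bootstrap_support"))
  breed_of <- support$breed_of
  sizes <- table(breed_of)
  eligible <- names(breed_of)[breed_of != support$outgroup &
                                sizes[breed_of] > 1L]
  if (threshold <= 0) return(character(0))
  flagged <- eligible[support$dog_placement[eligible] < threshold]
  unname(flagged)
}

#' Write a tree with support labels as Newick
#'
#' @param x a `bootstrap_phylo` or [ape::phylo].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree <- function(x, path) {
  tr <- if (inherits(x, "bootstrap_phylo")) x$consensus else x
  ape::write.tree(tr, file = path)
  invisible(path)
}
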