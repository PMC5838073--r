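#' @title Cohort data model
#' @name cohort
#' @description
#' A `cohort` is the universal in-memory object consumed by every analysis in
#' breedscape. It bundles a marker map, a diploid genotype matrix and the
#' per-sample population labels. Genotypes are coded as the count of the
#' second (alternate) allele: `0` = homozygous for allele 1, `1` =
#' heterozygous, `2` = homozygous for allele 2, `NA` = missing. The missing
#' code is a dedicated sentinel and is never conflated with the reference
#' homozygote.
#'
#' Coordinates are 1-based physical base pairs throughout (PLINK convention);
#' a segment spanning markers at positions `s..e` has length `e - s + 1` bp.
NULL

#' Construct a cohort
#'
#' @param map data.frame with columns `chrom` (character), `id` (marker id),
#'   `cM` (genetic position, may be 0), `pos` (1-based bp, strictly increasing
#'   within chromosome), `a1`, `a2` (allele symbols), and optionally
#'   `autosomal` (logical, default `TRUE`).
#' @param geno integer matrix, samples x markers, values in `{0, 1, 2, NA}`.
#'   Row names are ignored; sample identity comes from `samples$id`.
#' @param samples data.frame with columns `id` (unique), `breed` (non-empty),
#'   and optionally `country` and `clade`.
#' @return An object of class `cohort`.
#' @export
new_cohort <- function(map, geno, samples) {
  map <- as.data.frame(map)
  samples <- as.data.frame(samples)
  if (is.null(map$autosomal)) map$autosomal <- rep(TRUE, nrow(map))
  if (is.null(samples$country)) samples$country <- rep(NA_character_, nrow(samples))
  if (is.null(samples$clade)) samples$clade <- rep(NA_character_, nrow(samples))
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  obj <- structure(
    list(map = map, geno = geno, samples = samples),
    class = "cohort"
  )
  validate_cohort(obj)
  obj
}

#' Validate cohort invariants
#'
#' Checks shape agreement, sorted unique positions within chromosomes,
#' genotype codes, unique sample ids and non-empty breed labels.
#'
#' @param x a `cohort`.
#' @return `x`, invisibly; stops on violation.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  need <- c("chrom", "id", "cM", "pos", "a1", "a2")
  if (!all(need %in% names(x$map))) {
    stop("cohort map lacks columns: ", paste(setdiff(need, names(x$map)), collapse = ", "))
  }
  if (nrow(x$samples) != nrow(x$geno) || nrow(x$map) != ncol(x$geno)) {
    stop("cohort shapes disagree: ", nrow(x$samples), " samples x ",
         nrow(x$map), " markers vs genotype matrix ",
         nrow(x$geno), " x ", ncol(x$geno))
  }
  if (anyDuplicated(x$samples$id)) stop("duplicate sample ids in cohort")
  if (any(is.na(x$samples$breed) | x$samples$breed == "")) {
    stop("every sample needs a non-empty breed label")
  }
  for (ch in unique(x$map$chrom)) {
    p <- x$map$pos[x$map$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions not strictly increasing on chromosome ", ch)
    g <- x$map$cM[x$map$chrom == ch]
    if (!all(is.na(g)) && any(diff(g) < 0)) {
      stop("genetic positions decrease on chromosome ", ch)
    }
  }
  bad <- x$geno[!is.na(x$geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype codes outside {0, 1, 2, NA}")
  }
  invisible(x)
}

#' Construct a phased cohort
#'
#' Haplotype alleles are coded `0` (allele 1), `1` (allele 2) or `NA`.
#' Haplotypes are stored as a `(2 * n_samples) x n_markers` matrix with rows
#' interleaved: sample 1 haplotype 1, sample 1 haplotype 2, sample 2
#' haplotype 1, ...
#'
#' @param map as in [new_cohort()].
#' @param hap integer matrix of haplotype alleles, `2 * nrow(samples)` rows.
#' @param samples as in [new_cohort()].
#' @return An object of class `phased_cohort`.
#' @export
new_phased_cohort <- function(map, hap, samples) {
  map <- as.data.frame(map)
  samples <- as.data.frame(samples)
  if (is.null(map$autosomal)) map$autosomal <- TRUE
  if (is.null(samples$country)) samples$country <- NA_character_
  if (is.null(samples$clade)) samples$clade <- NA_character_
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  if (nrow(hap) != 2L * nrow(samples)) {
    stop("phased cohort needs exactly two haplotypes per sample")
  }
  if (ncol(hap) != nrow(map)) stop("haplotype matrix does not match marker map")
  bad <- hap[!is.na(hap)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 1L)) {
    stop("haplotype alleles outside {0, 1, NA}")
  }
  if (anyDuplicated(samples$id)) stop("duplicate sample ids")
  structure(list(map = map, hap = hap, samples = samples), class = "phased_cohort")
}

#' Collapse a phased cohort to unphased genotypes
#'
#' @param x a `phased_cohort`.
#' @return A `cohort` with genotypes equal to the haplotype allele sums.
#' @export
unphase <- function(x) {
  stopifnot(inherits(x, "phased_cohort"))
  n <- nrow(x$samples)
  g <- x$hap[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    x$hap[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  new_cohort(x$map, g, x$samples)
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$samples), " samples x ", nrow(x$map), " markers; ",
      length(unique(x$samples$breed)), " populations\n", sep = "")
  miss <- mean(is.na(x$geno))
  cat("  missingness ", sprintf("%.2f%%", 100 * miss), "; chromosomes: ",
      paste(unique(x$map$chrom), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
print.phased_cohort <- function(x, ...) {
  cat("<phased_cohort> ", nrow(x$samples), " samples (",
      nrow(x$hap), " haplotypes) x ", nrow(x$map), " markers\n", sep = "")
  invisible(x)
}

#' Subset a cohort by sample and/or marker index
#'
#' @param x a `cohort`.
#' @param samples integer/logical/character index into the sample table.
#' @param markers integer/logical index into the marker map.
#' @return The subset `cohort`.
#' @export
subset_cohort <- function(x, samples = NULL, markers = NULL) {
  stopifnot(inherits(x, "cohort"))
  si <- if (is.null(samples)) seq_len(nrow(x$samples)) else samples
  if (is.character(si)) si <- match(si, x$samples$id)
  mi <- if (is.null(markers)) seq_len(nrow(x$map)) else markers
  new_cohort(
    x$map[mi, , drop = FALSE],
    x$geno[si, mi, drop = FALSE],
    x$samples[si, , drop = FALSE]
  )
}

#' Per-sample and per-marker call rates
#'
#' @param x a `cohort`.
#' @return List with `sample` and `marker` call-rate vectors in `[0, 1]`.
#' @export
call_rates <- function(x) {
  stopifnot(inherits(x, "cohort"))
  ok <- !is.na(x$geno)
  list(
    sample = rowMeans(ok),
    marker = colMeans(ok)
  )
}

# Interval helpers shared by the ROH and haplotype-sharing code.
# Intervals are 1-based inclusive [start, end]; length = end - start + 1.

# Union length of a set of intervals (two-column matrix start, end).
interval_union_length <- function(start, end) {
  if (length(start) == 0L) return(0)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  total <- 0
  cs <- start[1L]; ce <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= ce + 1) {
      if (end[i] > ce) ce <- end[i]
    } else {
      total <- total + (ce - cs + 1)
      cs <- start[i]; ce <- end[i]
    }
  }
  total + (ce - cs + 1)
}

# Merge intervals into a disjoint sorted set (matrix with start,end columns).
interval_union <- function(start, end) {
  if (length(start) == 0L) {
    return(cbind(start = numeric(0), end = numeric(0)))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  os <- oe <- numeric(length(start))
  k <- 1L
  os[1L] <- start[1L]; oe[1L] <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= oe[k] + 1) {
      if (end[i] > oe[k]) oe[k] <- end[i]
    } else {
      k <- k + 1L
      os[k] <- start[i]; oe[k] <- end[i]
    }
  }
  cbind(start = os[seq_len(k)], end = oe[seq_len(k)])
}

# Total length of the intersection of two disjoint sorted interval sets.
interval_intersect_length <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  total <- 0
  i <- 1L; j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    lo <- max(a[i, 1L], b[j, 1L])
    hi <- min(a[i, 2L], b[j, 2L])
    if (hi >= lo) total <- total + (hi - lo + 1)
    if (a[i, 2L] < b[j, 2L]) i <- i + 1L else j <- j + 1L
  }
  total
}

# Deterministic per-stage seed derivation from one global seed.
# Keeps results reproducible while preventing stage-to-stage stream overlap.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- c(simulate = 101L, qc = 211L, subsample = 307L, phylo = 401L,
            metrics = 503L, sharing = 601L, report = 701L)
  o <- offs[[stage]]
  as.integer((as.numeric(seed) * 7919 + o * 104729) %% 2147483647)
}
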