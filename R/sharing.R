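#' @title Identity-by-descent haplotype sharing and divergence dating
#' @name haplotype_sharing
#' @description
#' Shared haplotypes between two individuals are reconstructed directly from
#' phased data with a sliding-window detector: windows of `window` SNPs
#' advancing by `step` match when the two haplotypes agree at every SNP typed
#' in both; runs of matching windows become candidate segments whose ends are
#' then refined marker-by-marker, tolerating up to `trim` mismatching
#' terminal markers. All four haplotype pairings of a sample pair are
#' scanned; the per-pair sharing sum is the union of their physical
#' projections, so overlap between pairings is never double counted.
#'
#' Cross-clade breed-pair medians of the pair sums (zeros included) form the
#' empirical null; pairs whose median exceeds the 95th percentile of all
#' cross-clade medians are significant. Divergence dating converts a median
#' shared length L (in cM) to generations as `g = 100 / (2 L)` — the
#' expected-length relation for a segment inherited from a common ancestor g
#' generations back — baselined against within-breed sharing.
NULL

#' Haplotype-sharing detector parameters
#'
#' @param window window size in SNPs (default 100).
#' @param step window step in SNPs (default 40).
#' @param trim maximum mismatching terminal markers discarded while refining
#'   each segment end (default 10).
#' @param min_len minimum reported segment length in bp (default 1e6).
#' @param percentile significance percentile over cross-clade breed-pair
#'   medians (default 95).
#' @param seed random seed (reserved for subsampling extensions).
#' @return A `sharing_params` list.
#' @export
sharing_params <- function(window = 100L, step = 40L, trim = 10L,
                           min_len = 1e6, percentile = 95, seed = 1L) {
  stopifnot(step <= window, trim < window, percentile > 0, percentile < 100)
  structure(list(window = as.integer(window), step = as.integer(step),
                 trim = as.integer(trim), min_len = min_len,
                 percentile = percentile, seed = as.integer(seed)),
            class = "sharing_params")
}

#' Divergence-dating parameters
#'
#' @param gen_years generation interval in years (default 4.5).
#' @param ref_year reference collection year (default 2016).
#' @param cM_per_Mb constant for bp-to-cM conversion (default 1, a uniform
#'   map approximation).
#' @return A `timing_params` list.
#' @export
timing_params <- function(gen_years = 4.5, ref_year = 2016, cM_per_Mb = 1) {
  stopifnot(gen_years > 0)
  structure(list(gen_years = gen_years, ref_year = ref_year,
                 cM_per_Mb = cM_per_Mb),
            class = "timing_params")
}

# matching segments of one haplotype pairing on one chromosome.
# h1, h2: allele vectors; pos: positions. Returns matrix (start, end) in bp.
shared_segments_pairing <- function(h1, h2, pos, params) {
  L <- length(h1)
  W <- params$window
  if (L < W) return(cbind(start = numeric(0), end = numeric(0)))
  co <- !is.na(h1) & !is.na(h2)
  mm <- co & (h1 != h2)
  match_ok <- co & !mm
  cmm <- cumsum(c(0L, mm))
  starts <- seq(1L, L - W + 1L, by = params$step)
  win_ok <- (cmm[starts + W] - cmm[starts]) == 0L
  if (!any(win_ok)) return(cbind(start = numeric(0), end = numeric(0)))
  r <- rle(win_ok)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  keep <- which(r$values)
  segs <- matrix(numeric(0), 0L, 2L)
  for (k in keep) {
    s_idx <- starts[lo[k]]
    e_idx <- starts[hi[k]] + W - 1L
    # refine: extend each end marker-by-marker, discarding up to `trim`
    # mismatching terminal markers; boundary rests on a matching marker
    if (e_idx < L) {
      idx <- (e_idx + 1L):L
      cm <- cumsum(mm[idx])
      lim <- which(cm > params$trim)[1L]
      if (!is.na(lim)) idx <- idx[seq_len(lim - 1L)]
      good <- idx[match_ok[idx]]
      if (length(good)) e_idx <- max(e_idx, good[length(good)])
    }
    if (s_idx > 1L) {
      idx <- (s_idx - 1L):1L
      cm <- cumsum(mm[idx])
      lim <- which(cm > params$trim)[1L]
      if (!is.na(lim)) idx <- idx[seq_len(lim - 1L)]
      good <- idx[match_ok[idx]]
      if (length(good)) s_idx <- min(s_idx, good[length(good)])
    }
    segs <- rbind(segs, c(pos[s_idx], pos[e_idx]))
  }
  segs <- interval_union(segs[, 1L], segs[, 2L])
  segs[segs[, 2L] - segs[, 1L] + 1 >= params$min_len, , drop = FALSE]
}

#' Detect shared haplotype segments for a sample pair
#'
#' @param phased a `phased_cohort`.
#' @param a,b sample ids.
#' @param params a [sharing_params()] set.
#' @return data.frame with columns `a`, `b`, `chrom`, `start`, `end`,
#'   `pairing` (`"11"`, `"12"`, `"21"`, `"22"`), `length`.
#' @export
detect_shared_segments <- function(phased, a, b, params = sharing_params()) {
  stopifnot(inherits(phased, "phased_cohort"))
  ia <- match(a, phased$samples$id)
  ib <- match(b, phased$samples$id)
  if (is.na(ia) || is.na(ib)) stop("unknown sample id")
  out <- list()
  for (ch in unique(phased$map$chrom)) {
    mi <- which(phased$map$chrom == ch)
    pos <- phased$map$pos[mi]
    for (i in 1:2) {
      ha <- phased$hap[2L * (ia - 1L) + i, mi]
      for (j in 1:2) {
        hb <- phased$hap[2L * (ib - 1L) + j, mi]
        seg <- shared_segments_pairing(ha, hb, pos, params)
        if (nrow(seg)) {
          out[[length(out) + 1L]] <- data.frame(
            a = a, b = b, chrom = ch, start = seg[, 1L], end = seg[, 2L],
            pairing = paste0(i, j), stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(a = character(0), b = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      pairing = character(0), length = numeric(0)))
  }
  res <- do.call(rbind, out)
  res$length <- res$end - res$start + 1
  rownames(res) <- NULL
  res
}

#' Total shared length for one sample pair
#'
#' Projects all four pairings' segments to physical coordinates, takes the
#' per-chromosome interval union and sums lengths, so overlapping segments
#' are counted once.
#'
#' @param segments [detect_shared_segments()] output for one pair.
#' @return Total shared length in bp (0 for no segments).
#' @export
pair_sharing_sum <- function(segments) {
  if (nrow(segments) == 0L) return(0)
  total <- 0
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    total <- total + interval_union_length(s$start, s$end)
  }
  total
}

#' Sharing sums for many sample pairs
#'
#' @param phased a `phased_cohort`.
#' @param pairs two-column data.frame/matrix of sample-id pairs; default all
#'   unordered cross-breed pairs.
#' @param params a [sharing_params()] set.
#' @return data.frame `a`, `b`, `bp` (zeros included for non-sharing pairs).
#' @export
all_pair_sharing <- function(phased, pairs = NULL, params = sharing_params()) {
  stopifnot(inherits(phased, "phased_cohort"))
  if (is.null(pairs)) {
    ids <- phased$samples$id
    breed <- phased$samples$breed
    idx <- utils::combn(length(ids), 2L)
    cross <- breed[idx[1L, ]] != breed[idx[2L, ]]
    pairs <- data.frame(a = ids[idx[1L, cross]], b = ids[idx[2L, cross]],
                        stringsAsFactors = FALSE)
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs)[1:2] <- c("a", "b")
  bp <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    bp[k] <- pair_sharing_sum(
      detect_shared_segments(phased, pairs$a[k], pairs$b[k], params)
    )
  }
  data.frame(a = pairs$a, b = pairs$b, bp = bp, stringsAsFactors = FALSE)
}

#' Median cross-clade sharing per breed pair
#'
#' For every unordered pair of breeds from different clades, the median of
#' the per-dog-pair sharing sums over all inter-breed dog pairs, with zeros
#' for pairs absent from `sums` (the even-count median is the mean of the
#' central two values).
#'
#' @param sums data.frame `a`, `b`, `bp` from [all_pair_sharing()].
#' @param samples sample table with `id`, `breed`, `clade`.
#' @param within_clade include same-clade breed pairs too (default `FALSE`;
#'   the empirical null uses cross-clade pairs only).
#' @return data.frame `breed_a`, `breed_b`, `clade_a`, `clade_b`, `n_pairs`,
#'   `median_bp`.
#' @export
breed_pair_medians <- function(sums, samples, within_clade = FALSE) {
  breeds <- unique(samples$breed)
  clade_of <- stats::setNames(samples$clade, samples$id)
  breed_clade <- stats::setNames(
    samples$clade[match(breeds, samples$breed)], breeds
  )
  key <- paste(pmin(sums$a, sums$b), pmax(sums$a, sums$b))
  bp_of <- stats::setNames(sums$bp, key)
  rows <- list()
  for (i in seq_along(breeds)) {
    for (j in seq_along(breeds)) {
      if (i >= j) next
      ba <- breeds[i]; bb <- breeds[j]
      if (!within_clade &&
          (is.na(breed_clade[ba]) || is.na(breed_clade[bb]) ||
           breed_clade[ba] == breed_clade[bb])) next
      da <- samples$id[samples$breed == ba]
      db <- samples$id[samples$breed == bb]
      if (length(da) == 0L || length(db) == 0L) next
      grid <- expand.grid(a = da, b = db, stringsAsFactors = FALSE)
      k <- paste(pmin(grid$a, grid$b), pmax(grid$a, grid$b))
      v <- bp_of[k]
      v[is.na(v)] <- 0
      rows[[length(rows) + 1L]] <- data.frame(
        breed_a = ba, breed_b = bb,
        clade_a = breed_clade[[ba]], clade_b = breed_clade[[bb]],
        n_pairs = length(v), median_bp = stats::median(v),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(breed_a = character(0), breed_b = character(0),
                      clade_a = character(0), clade_b = character(0),
                      n_pairs = integer(0), median_bp = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Empirical significance threshold over cross-clade medians
#'
#' The chosen percentile (linear interpolation between order statistics,
#' i.e. [stats::quantile()] type 7) of all cross-clade breed-pair medians.
#' Significance is strict: a pair is flagged only when its median lies
#' strictly above the threshold.
#'
#' @param stats a [breed_pair_medians()] table.
#' @param percentile percentile in (0, 100), default 95.
#' @return The threshold in bp.
#' @export
significance_threshold <- function(stats, percentile = 95) {
  if (nrow(stats) == 0L) stop("no cross-clade breed pairs")
  if (nrow(stats) < 20L) {
    warning("only ", nrow(stats), " cross-clade breed pairs; the empirical ",
            "percentile is unstable below ~20")
  }
  unname(stats::quantile(stats$median_bp, percentile / 100, type = 7))
}

#' Flag significant breed pairs
#'
#' @param stats a [breed_pair_medians()] table.
#' @param threshold bp threshold from [significance_threshold()].
#' @return `stats` with a logical `significant` column (strictly above).
#' @export
flag_significant <- function(stats, threshold) {
  stats$significant <- stats$median_bp > threshold
  stats
}

#' Date the divergence of a breed pair from median sharing
#'
#' Shared length L (median pair sum, converted to cM) maps to generations
#' since the common ancestor as `g(L) = 100 / (2 L)`. The reported time is
#' `g(median_AB) - g(min(median_AA, median_BB))` generations, i.e. the
#' cross-breed depth in excess of the breeds' own internal sharing depth,
#' converted to years. A non-positive year count means the two populations
#' share as much as a single population does internally and are flagged
#' `same_population`.
#'
#' @param median_ab cross-breed median sharing (bp).
#' @param median_aa,median_bb within-breed median sharing (bp); if both are
#'   non-positive the baseline term is omitted (with a message).
#' @param timing a [timing_params()] set.
#' @return List: `generations`, `years`, `calendar_year`, `same_population`.
#'   All `NA` when `median_ab <= 0` (no detectable shared history).
#' @export
divergence_time <- function(median_ab, median_aa = NA, median_bb = NA,
                            timing = timing_params()) {
  stopifnot(inherits(timing, "timing_params"))
  if (is.na(median_ab) || median_ab <= 0) {
    return(list(generations = NA_real_, years = NA_real_,
                calendar_year = NA_real_, same_population = NA))
  }
  to_cM <- function(bp) bp / 1e6 * timing$cM_per_Mb
  ghat <- function(bp) 100 / (2 * to_cM(bp))
  g_ab <- ghat(median_ab)
  wd <- c(median_aa, median_bb)
  wd <- wd[!is.na(wd) & wd > 0]
  g_base <- if (length(wd)) ghat(min(wd)) else {
    message("divergence_time: no positive within-breed baseline; term omitted")
    0
  }
  gens <- g_ab - g_base
  years <- gens * timing$gen_years
  list(generations = gens, years = years,
       calendar_year = timing$ref_year - years,
       same_population = years <= 0)
}

#' Export the significant-sharing network as TSV
#'
#' @param stats a flagged [breed_pair_medians()] table (see
#'   [flag_significant()]), optionally carrying dating columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
sharing_network_export <- function(stats, path) {
  keep <- stats[!is.na(stats$significant) & stats$significant, , drop = FALSE]
  utils::write.table(keep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
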