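# Independent brute-force oracles and fixture builders. These deliberately
# use naive loop/discretisation algorithms, distinct from the package's
# implementations.

bf_ibs <- function(ga, gb) {
  ok <- !is.na(ga) & !is.na(gb)
  if (!any(ok)) return(NaN)
  mean(1 - abs(ga[ok] - gb[ok]) / 2)
}

bf_me <- function(ga, gb) {
  ok <- !is.na(ga) & !is.na(gb)
  sum((ga[ok] == 0 & gb[ok] == 2) | (ga[ok] == 2 & gb[ok] == 0))
}

# sliding-window ROH caller, written as explicit loops over windows
bf_roh <- function(g, pos, p) {
  L <- length(g)
  W <- p$window_snps
  empty <- data.frame(start = numeric(0), end = numeric(0), n_snps = integer(0))
  if (L < W) return(empty)
  nw <- L - W + 1
  win_ok <- vapply(seq_len(nw), function(i) {
    wg <- g[i:(i + W - 1)]
    sum(!is.na(wg) & wg == 1) <= p$window_max_het &&
      sum(is.na(wg)) <= p$window_max_missing
  }, logical(1))
  in_run <- vapply(seq_len(L), function(j) {
    wins <- max(1, j - W + 1):min(j, nw)
    mean(win_ok[wins]) >= p$hit_fraction
  }, logical(1))
  idx <- which(in_run)
  if (!length(idx)) return(empty)
  segs <- list()
  cur <- idx[1]
  last <- idx[1]
  for (k in idx[-1]) {
    if (k == last + 1 && pos[k] - pos[last] <= p$max_gap_kb * 1000) {
      last <- k
    } else {
      segs[[length(segs) + 1]] <- c(cur, last)
      cur <- k; last <- k
    }
  }
  segs[[length(segs) + 1]] <- c(cur, last)
  out <- do.call(rbind, lapply(segs, function(s) {
    data.frame(start = pos[s[1]], end = pos[s[2]], n_snps = s[2] - s[1] + 1)
  }))
  out[out$n_snps >= p$min_snps & (out$end - out$start + 1) >= p$min_kb * 1000, ,
      drop = FALSE]
}

# union length of 1-based inclusive integer intervals via coordinate
# compression (event-point sweep)
bf_union_length <- function(start, end) {
  if (!length(start)) return(0)
  pts <- sort(unique(c(start, end + 1)))
  total <- 0
  for (k in seq_len(length(pts) - 1)) {
    lo <- pts[k]; hi <- pts[k + 1] - 1
    if (any(start <= lo & end >= lo)) total <- total + (hi - lo + 1)
  }
  total
}

bf_median <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
}

# random-genotype cohort with per-marker allele frequencies
make_random_cohort <- function(n, L, seed = 1, miss = 0, n_breeds = 2,
                               chrom_count = 2) {
  set.seed(seed)
  freq <- runif(L, 0.1, 0.9)
  geno <- matrix(rbinom(n * L, 2, rep(freq, each = n)), n, L)
  if (miss > 0) geno[matrix(runif(n * L) < miss, n)] <- NA
  per <- ceiling(L / chrom_count)
  chrom <- paste0("chr", rep(seq_len(chrom_count), each = per)[seq_len(L)])
  pos <- unlist(lapply(split(seq_len(L), chrom), function(i) {
    sort(sample.int(1e8, length(i)))
  }), use.names = FALSE)
  map <- data.frame(chrom = sort(chrom), id = sprintf("snp%04d", seq_len(L)),
                    cM = 0, pos = pos, a1 = "A", a2 = "B",
                    stringsAsFactors = FALSE)
  samples <- data.frame(
    id = sprintf("s%02d", seq_len(n)),
    breed = paste0("br", rep_len(seq_len(n_breeds), n)),
    stringsAsFactors = FALSE
  )
  new_cohort(map, geno, samples)
}

# cohort from an explicit genotype matrix (one chromosome, evenly spaced)
mk_cohort <- function(geno, pos = NULL, breeds = NULL, spacing = 1e5) {
  geno <- as.matrix(geno)
  n <- nrow(geno); L <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(L) * spacing
  map <- data.frame(chrom = rep("chr1", L), id = sprintf("m%03d", seq_len(L)),
                    cM = rep(0, L), pos = pos, a1 = rep("A", L),
                    a2 = rep("B", L), stringsAsFactors = FALSE)
  if (is.null(breeds)) breeds <- rep("pop", n)
  new_cohort(map, geno,
             data.frame(id = sprintf("s%02d", seq_len(n)), breed = breeds,
                        stringsAsFactors = FALSE))
}

# phased cohort from explicit haplotype rows (one chromosome)
mk_phased <- function(hap, pos = NULL, breeds = NULL, spacing = 1e5,
                      clades = NULL) {
  hap <- as.matrix(hap)
  n <- nrow(hap) / 2; L <- ncol(hap)
  if (is.null(pos)) pos <- seq_len(L) * spacing
  map <- data.frame(chrom = "chr1", id = sprintf("m%03d", seq_len(L)), cM = 0,
                    pos = pos, a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  if (is.null(breeds)) breeds <- rep("pop", n)
  samples <- data.frame(id = sprintf("s%02d", seq_len(n)), breed = breeds,
                        stringsAsFactors = FALSE)
  if (!is.null(clades)) samples$clade <- clades
  new_phased_cohort(map, hap, samples)
}

# hand-built truth record from explicit mosaics:
# mosaics = list(sample_id = list(hap1 = list(chr = list(end, fnd)), hap2 = ...))
mk_truth <- function(mosaics, chrom_lengths) {
  structure(
    list(mosaics = mosaics, chrom_lengths = chrom_lengths,
         founder_freq = NULL, split_gens = NULL,
         samples = data.frame(id = names(mosaics),
                              breed = "pop", stringsAsFactors = FALSE),
         config = list(generations = NA)),
    class = "truth_record"
  )
}
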