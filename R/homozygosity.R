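#' @title Homozygosity metrics and breed-status classification
#' @name homozygosity_metrics
#' @description
#' Four per-breed metrics computed from SNP-array genotypes:
#'
#' * single-dog LnH — summed length of runs of homozygosity (ROH), averaged
#'   over the breed's dogs, in Mb;
#' * shared LnH — total length of intervals where `k = min(10, n)` dogs of the
#'   breed are simultaneously inside a ROH and homozygous for the same allele
#'   at every co-typed SNP (defined for breeds with at least five dogs);
#' * decay rate — the exponential rate at which shared homozygosity shrinks
#'   as dogs are added, fitted on the log scale over random dog orderings;
#' * F — the method-of-moments SNP-based inbreeding coefficient
#'   `(O_hom - E_hom) / (L - E_hom)`, averaged over dogs.
#'
#' A population with at least five dogs qualifies as a breed when at least
#' three of the four metrics fall in the purebred range and the population is
#' phylogenetically monophyletic; with the metrics but without monophyly it
#' is a variety. ROH calling is sliding-window based; every parameter is a
#' configuration knob since array ROH conventions vary between studies.
NULL

#' ROH-calling and shared-homozygosity parameters
#'
#' Defaults follow the common array-data sliding-window convention.
#'
#' @param window_snps scanning window size in SNPs (default 50).
#' @param window_max_het maximum heterozygotes allowed per window (default 1).
#' @param window_max_missing maximum missing calls per window (default 5).
#' @param hit_fraction minimum fraction of spanning windows that must be
#'   homozygous for a SNP to be in-run (default 0.05).
#' @param min_snps minimum SNPs per reported segment (default 100).
#' @param min_kb minimum segment length in kb (default 1000).
#' @param max_gap_kb maximum gap between consecutive in-run SNPs before a
#'   segment is split (default 1000).
#' @param shared_min_kb minimum length of a shared-homozygosity interval
#'   (default 1000).
#' @param decay_orderings random dog orderings averaged in the decay-rate fit
#'   (default 20).
#' @return A `roh_params` list.
#' @export
roh_params <- function(window_snps = 50L, window_max_het = 1L,
                       window_max_missing = 5L, hit_fraction = 0.05,
                       min_snps = 100L, min_kb = 1000, max_gap_kb = 1000,
                       shared_min_kb = 1000, decay_orderings = 20L) {
  structure(list(window_snps = as.integer(window_snps),
                 window_max_het = as.integer(window_max_het),
                 window_max_missing = as.integer(window_max_missing),
                 hit_fraction = hit_fraction, min_snps = as.integer(min_snps),
                 min_kb = min_kb, max_gap_kb = max_gap_kb,
                 shared_min_kb = shared_min_kb,
                 decay_orderings = as.integer(decay_orderings)),
            class = "roh_params")
}

# per-chromosome in-run flags for one genotype vector
roh_in_run <- function(g, params) {
  L <- length(g)
  W <- params$window_snps
  if (L < W) return(rep(FALSE, L))
  het <- cumsum(c(0L, !is.na(g) & g == 1L))
  mis <- cumsum(c(0L, is.na(g)))
  nw <- L - W + 1L
  i <- seq_len(nw)
  win_ok <- (het[i + W] - het[i]) <= params$window_max_het &
    (mis[i + W] - mis[i]) <= params$window_max_missing
  cok <- cumsum(c(0L, win_ok))
  j <- seq_len(L)
  lo <- pmax(1L, j - W + 1L)
  hi <- pmin(j, nw)
  nwin <- hi - lo + 1L
  nok <- cok[hi + 1L] - cok[lo]
  nok / nwin >= params$hit_fraction
}

# split marker-index runs by position gaps, filter by size, return segments
runs_to_segments <- function(idx, pos, min_snps, min_kb, max_gap_kb) {
  if (length(idx) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0), n_snps = integer(0)))
  }
  brk <- c(TRUE, diff(idx) > 1L | diff(pos[idx]) > max_gap_kb * 1000)
  run_id <- cumsum(brk)
  out <- lapply(split(idx, run_id), function(ii) {
    data.frame(start = pos[ii[1L]], end = pos[ii[length(ii)]],
               n_snps = length(ii))
  })
  seg <- do.call(rbind, out)
  seg[seg$n_snps >= min_snps & (seg$end - seg$start + 1) >= min_kb * 1000, ,
      drop = FALSE]
}

#' Detect runs of homozygosity for one sample
#'
#' Sliding-window ROH calling: windows of `window_snps` SNPs allowing up to
#' `window_max_het` heterozygous and `window_max_missing` missing calls; a
#' SNP is in-run when at least `hit_fraction` of the windows spanning it are
#' homozygous; maximal runs are kept when they satisfy the SNP-count, length
#' and gap constraints.
#'
#' @param cohort a `cohort`.
#' @param sample sample id.
#' @param params a [roh_params()] set.
#' @return data.frame with columns `sample`, `chrom`, `start`, `end` (1-based
#'   inclusive bp), `n_snps`.
#' @export
detect_roh <- function(cohort, sample, params = roh_params()) {
  validate_cohort(cohort)
  i <- match(sample, cohort$samples$id)
  if (is.na(i)) stop("unknown sample id: ", sample)
  out <- list()
  for (ch in unique(cohort$map$chrom)) {
    mi <- which(cohort$map$chrom == ch)
    g <- cohort$geno[i, mi]
    pos <- cohort$map$pos[mi]
    inr <- roh_in_run(g, params)
    seg <- runs_to_segments(which(inr), pos, params$min_snps, params$min_kb,
                            params$max_gap_kb)
    if (nrow(seg)) {
      seg <- cbind(data.frame(sample = sample, chrom = ch,
                              stringsAsFactors = FALSE), seg)
      out[[length(out) + 1L]] <- seg
    }
  }
  if (!length(out)) {
    return(data.frame(sample = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0), n_snps = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summed ROH length for one dog, in Mb
#'
#' @param segments ROH segments of one sample ([detect_roh()] output).
#' @return Total length in Mb (`sum(end - start + 1) / 1e6`).
#' @export
single_dog_lnh <- function(segments) {
  if (nrow(segments) == 0L) return(0)
  sum(segments$end - segments$start + 1) / 1e6
}

# marker-level in-ROH indicator for one sample (list over chromosomes)
roh_marker_flags <- function(cohort, sample, params) {
  seg <- detect_roh(cohort, sample, params)
  flags <- rep(FALSE, nrow(cohort$map))
  if (nrow(seg)) {
    for (k in seq_len(nrow(seg))) {
      mi <- cohort$map$chrom == seg$chrom[k] &
        cohort$map$pos >= seg$start[k] & cohort$map$pos <= seg$end[k]
      flags[mi] <- TRUE
    }
  }
  flags
}

# shared homozygosity (Mb) for an explicit dog set, given precomputed
# per-dog in-ROH flags
shared_lnh_dogs <- function(cohort, dogs, params, flags_list) {
  idx <- match(dogs, cohort$samples$id)
  all_in <- Reduce(`&`, flags_list[dogs])
  g <- cohort$geno[idx, , drop = FALSE]
  any_het <- colSums(!is.na(g) & g == 1L) > 0L
  has0 <- colSums(!is.na(g) & g == 0L) > 0L
  has2 <- colSums(!is.na(g) & g == 2L) > 0L
  good <- all_in & !any_het & !(has0 & has2)
  total <- 0
  for (ch in unique(cohort$map$chrom)) {
    mi <- which(cohort$map$chrom == ch)
    seg <- runs_to_segments(which(good[mi]), cohort$map$pos[mi],
                            min_snps = 1L, min_kb = params$shared_min_kb,
                            max_gap_kb = params$max_gap_kb)
    if (nrow(seg)) total <- total + sum(seg$end - seg$start + 1)
  }
  total / 1e6
}

#' Shared homozygosity across dogs of a breed, in Mb
#'
#' Total length of intervals in which `k` dogs of the breed are all inside a
#' ROH and carry the same homozygous allele at every co-typed SNP. Defined
#' for breeds with at least five dogs; `k` defaults to `min(10, n)` randomly
#' selected dogs.
#'
#' @param cohort a `cohort`.
#' @param breed breed label.
#' @param k number of dogs intersected (default `min(10, n)`).
#' @param params a [roh_params()] set.
#' @param seed seed for the random dog selection.
#' @param dogs optional explicit dog ids (overrides `k`/`seed`).
#' @return Shared LnH in Mb, or `NA` (with a message) when the breed has
#'   fewer than five dogs.
#' @export
shared_lnh <- function(cohort, breed, k = NULL, params = roh_params(),
                       seed = 1L, dogs = NULL) {
  validate_cohort(cohort)
  members <- cohort$samples$id[cohort$samples$breed == breed]
  if (is.null(dogs)) {
    n <- length(members)
    if (n < 5L) {
      message("shared_lnh undefined for ", breed, " (n = ", n, " < 5)")
      return(NA_real_)
    }
    if (is.null(k)) k <- min(10L, n)
    set.seed(seed)
    dogs <- if (n > k) sort(sample(members, k)) else members
  }
  flags <- lapply(stats::setNames(dogs, dogs),
                  function(d) roh_marker_flags(cohort, d, params))
  shared_lnh_dogs(cohort, dogs, params, flags)
}

#' Decay rate of shared homozygosity
#'
#' For `k = 2..min(10, n)`, `S_k` is the mean over `decay_orderings` random
#' dog orderings of the shared LnH of the first `k` dogs. The decay rate `r`
#' is minus the least-squares slope of `ln S_k` on `k` over the points with
#' `S_k > 0`.
#'
#' @param cohort a `cohort`.
#' @param breed breed label (needs at least five dogs).
#' @param params a [roh_params()] set.
#' @param seed random seed (orderings are reproducible).
#' @return List with `rate`, the `S_k` profile (`k`, `S_k`), and the dog
#'   count; `rate` is `NA` when undefined (all `S_k` zero or fewer than two
#'   positive points).
#' @export
decay_rate <- function(cohort, breed, params = roh_params(), seed = 1L) {
  validate_cohort(cohort)
  members <- cohort$samples$id[cohort$samples$breed == breed]
  n <- length(members)
  if (n < 5L) {
    message("decay_rate undefined for ", breed, " (n = ", n, " < 5)")
    return(list(rate = NA_real_, profile = NULL, n = n))
  }
  kmax <- min(10L, n)
  set.seed(seed)
  flags <- lapply(stats::setNames(members, members),
                  function(d) roh_marker_flags(cohort, d, params))
  R <- params$decay_orderings
  S <- matrix(0, R, kmax - 1L)
  for (r in seq_len(R)) {
    ord <- sample(members)
    for (k in 2:kmax) {
      S[r, k - 1L] <- shared_lnh_dogs(cohort, ord[seq_len(k)], params, flags)
    }
  }
  Sk <- colMeans(S)
  ks <- 2:kmax
  pos <- Sk > 0
  if (sum(pos) < 2L) {
    return(list(rate = NA_real_, profile = data.frame(k = ks, S_k = Sk), n = n))
  }
  fit <- stats::lm(log(Sk[pos]) ~ ks[pos])
  list(rate = -unname(stats::coef(fit)[2L]),
       profile = data.frame(k = ks, S_k = Sk), n = n)
}

#' SNP-based method-of-moments inbreeding coefficient
#'
#' `F = (O_hom - E_hom) / (L - E_hom)` where `O_hom` is the observed
#' homozygous count over the sample's non-missing markers and
#' `E_hom = sum(1 - 2 p (1 - p))` over the same markers. Frequencies default
#' to the full cohort; pass `freq` to use a reference panel (F is always
#' relative to a frequency reference).
#'
#' @param cohort a `cohort`.
#' @param sample sample id, or `NULL` for all samples.
#' @param freq optional per-marker allele-2 frequencies.
#' @return Named numeric vector of F values in `[-1, 1]` (NA when the
#'   denominator degenerates).
#' @export
inbreeding_f <- function(cohort, sample = NULL, freq = NULL) {
  validate_cohort(cohort)
  p <- if (is.null(freq)) colMeans(cohort$geno, na.rm = TRUE) / 2 else freq
  stopifnot(length(p) == ncol(cohort$geno))
  ids <- if (is.null(sample)) cohort$samples$id else sample
  out <- stats::setNames(numeric(length(ids)), ids)
  e_marker <- 1 - 2 * p * (1 - p)
  for (s in ids) {
    i <- match(s, cohort$samples$id)
    if (is.na(i)) stop("unknown sample id: ", s)
    g <- cohort$geno[i, ]
    ok <- !is.na(g) & !is.na(p)
    L <- sum(ok)
    O <- sum(g[ok] != 1L)
    E <- sum(e_marker[ok])
    out[s] <- if (abs(L - E) < 1e-9) NA_real_ else (O - E) / (L - E)
  }
  out
}

#' Purebred metric thresholds
#'
#' The purebred ranges against which breed metrics are tested: single-dog
#' LnH at least 1098.365 Mb, shared LnH at least 48.092 Mb, decay at most
#' 0.607, F at least 0.133; status is assessed for populations of at least
#' five dogs, requiring 3 of the 4 metrics in range.
#'
#' @param lnh_min,shared_min,decay_max,f_min metric thresholds.
#' @param min_n minimum dogs for a status call (default 5).
#' @param required,total the "required of total" metric rule (default 3 of 4).
#' @return A `status_thresholds` list.
#' @export
status_thresholds <- function(lnh_min = 1098.365, shared_min = 48.092,
                              decay_max = 0.607, f_min = 0.133,
                              min_n = 5L, required = 3L, total = 4L) {
  structure(list(lnh_min = lnh_min, shared_min = shared_min,
                 decay_max = decay_max, f_min = f_min,
                 min_n = as.integer(min_n), required = as.integer(required),
                 total = as.integer(total)),
            class = "status_thresholds")
}

#' Classify a population's breed status
#'
#' Populations with fewer than `min_n` dogs are `Insufficient`. Otherwise a
#' population passing the metric rule is a `Breed` if monophyletic and a
#' `Variety` if not; failing the metric rule it is `NotBreed`. A metric that
#' is undefined (`NA`, e.g. shared LnH for a breed that was measured with too
#' few dogs) counts as neither pass nor fail: the required count is rescaled
#' to `ceiling(required / total * available)`.
#'
#' @param n dogs sampled.
#' @param f,lnh,shared,decay the four metrics (NA allowed).
#' @param monophyletic logical; `NA` is treated as not monophyletic.
#' @param thresholds a [status_thresholds()] set.
#' @return List of class `status_call`: `status` (one of `"Breed"`,
#'   `"Variety"`, `"NotBreed"`, `"Insufficient"`), `passes` (named logical),
#'   `rationale`.
#' @export
classify_status <- function(n, f, lnh, shared, decay, monophyletic,
                            thresholds = status_thresholds()) {
  passes <- c(
    f = if (is.na(f)) NA else f >= thresholds$f_min,
    lnh = if (is.na(lnh)) NA else lnh >= thresholds$lnh_min,
    shared = if (is.na(shared)) NA else shared >= thresholds$shared_min,
    decay = if (is.na(decay)) NA else decay <= thresholds$decay_max
  )
  if (n < thresholds$min_n) {
    return(structure(list(status = "Insufficient", passes = passes,
                          rationale = sprintf("n = %d < %d", n, thresholds$min_n)),
                     class = "status_call"))
  }
  avail <- sum(!is.na(passes))
  need <- ceiling(thresholds$required / thresholds$total * avail)
  npass <- sum(passes, na.rm = TRUE)
  mono <- isTRUE(monophyletic)
  status <- if (npass >= need && avail > 0L) {
    if (mono) "Breed" else "Variety"
  } else {
    "NotBreed"
  }
  structure(list(status = status, passes = passes,
                 rationale = sprintf("%d of %d available metrics in range (need %d); %smonophyletic",
                                     npass, avail, need, if (mono) "" else "not ")),
            class = "status_call")
}

#' @export
print.status_call <- function(x, ...) {
  cat("<status_call> ", x$status, " — ", x$rationale, "\n", sep = "")
  invisible(x)
}

#' Compute the full per-breed metric table
#'
#' Runs ROH detection, single and shared LnH, decay rate and F for every
#' breed, attaches monophyly flags, and classifies status.
#'
#' @param cohort a `cohort`.
#' @param monophyly named logical vector (breed -> monophyletic), e.g. from
#'   thresholding [breed_monophyly()] supports; missing breeds default to
#'   `NA`.
#' @param params a [roh_params()] set.
#' @param thresholds a [status_thresholds()] set.
#' @param freq optional reference allele frequencies for F.
#' @param seed seed for shared-LnH dog selection and decay orderings.
#' @return data.frame with one row per breed: `breed`, `n`, `f`, `lnh_mb`,
#'   `shared_lnh_mb`, `decay`, `monophyletic`, `status`.
#' @export
breed_metrics <- function(cohort, monophyly = NULL, params = roh_params(),
                          thresholds = status_thresholds(), freq = NULL,
                          seed = 1L) {
  validate_cohort(cohort)
  fvals <- inbreeding_f(cohort, freq = freq)
  breeds <- unique(cohort$samples$breed)
  rows <- vector("list", length(breeds))
  for (bi in seq_along(breeds)) {
    b <- breeds[bi]
    dogs <- cohort$samples$id[cohort$samples$breed == b]
    n <- length(dogs)
    lnh <- mean(vapply(dogs, function(d) single_dog_lnh(detect_roh(cohort, d, params)),
                       numeric(1)))
    sh <- suppressMessages(shared_lnh(cohort, b, params = params,
                                      seed = derive_seed(seed, "metrics") + bi))
    dc <- suppressMessages(decay_rate(cohort, b, params = params,
                                      seed = derive_seed(seed, "metrics") + bi))$rate
    mono <- if (!is.null(monophyly) && b %in% names(monophyly)) monophyly[[b]] else NA
    st <- classify_status(n, mean(fvals[dogs]), lnh, sh, dc, mono, thresholds)
    rows[[bi]] <- data.frame(
      breed = b, n = n, f = mean(fvals[dogs]), lnh_mb = lnh,
      shared_lnh_mb = sh, decay = dc, monophyletic = if (is.na(mono)) NA else mono,
      status = st$status, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published Italian-breed metric table
#'
#' The printed per-population metric values (sample size, F, single-dog LnH,
#' shared LnH, decay, phylogenetic clustering, assigned status) for the 23
#' Italian dog populations, usable as worked examples for the status
#' classifier. Populations measured in two countries or combined with a
#' sibling population carry a `combined_with` note.
#'
#' @return data.frame.
#' @export
italian_breed_metrics <- function() {
  path <- system.file("extdata", "italian_breed_metrics.tsv",
                      package = "breedscape", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", quote = "")
}
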