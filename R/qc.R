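#' @title Marker and sample quality control
#' @name qc_filters
#' @description
#' SNP-array data editing as pure functions on a cohort, applied in a fixed
#' order: marker filters (autosomes, call rate, minor allele frequency), then
#' sample call-rate filtering, then duplicate removal by identity-by-state,
#' then relatedness pruning by discordant-homozygote count (Mendelian error,
#' ME).
#'
#' ME is an absolute count, so it scales with marker number: the conventional
#' threshold of 100 discordant homozygotes refers to a ~142,840-marker array.
#' With `me_scale = TRUE` (default) the threshold is rescaled proportionally
#' to the cohort's marker count, so that QC behaves sensibly on sparser
#' panels.
NULL

#' QC parameter set
#'
#' @param marker_call_rate minimum marker call rate (default 0.95; markers
#'   below are removed).
#' @param maf_min minimum minor allele frequency. The conventional printed
#'   value 0.01% (0.0001) is taken literally as the default even though it is
#'   below the resolution of most cohorts; 0.01 (1%) is the common practical
#'   choice and can be set here.
#' @param sample_call_rate minimum sample call rate (default 0.90; samples
#'   strictly below are removed, so a sample at exactly 90% is retained).
#' @param duplicate_ibs IBS threshold above which a pair is a duplicate
#'   (strict `>`, default 0.99).
#' @param me_max pairs with discordant-homozygote count strictly below this
#'   are treated as close relatives (default 100).
#' @param me_ref_markers marker count at which `me_max` is calibrated
#'   (default 142840).
#' @param me_scale rescale `me_max` proportionally to the cohort marker count
#'   (default `TRUE`).
#' @param autosome_only drop non-autosomal markers first (default `TRUE`).
#' @return A `qc_params` list.
#' @export
qc_params <- function(marker_call_rate = 0.95,
                      maf_min = 0.0001,
                      sample_call_rate = 0.90,
                      duplicate_ibs = 0.99,
                      me_max = 100,
                      me_ref_markers = 142840,
                      me_scale = TRUE,
                      autosome_only = TRUE) {
  p <- list(marker_call_rate = marker_call_rate, maf_min = maf_min,
            sample_call_rate = sample_call_rate, duplicate_ibs = duplicate_ibs,
            me_max = me_max, me_ref_markers = me_ref_markers,
            me_scale = me_scale, autosome_only = autosome_only)
  rates <- c(marker_call_rate, maf_min, sample_call_rate, duplicate_ibs)
  stopifnot(all(rates >= 0 & rates <= 1), me_max >= 0)
  class(p) <- "qc_params"
  p
}

qc_report <- function(rule, removed_ids, n_in, n_out, unit) {
  structure(
    list(rule = rule, removed = removed_ids, n_in = n_in, n_out = n_out,
         unit = unit),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", x$rule, ": ", x$n_in, " -> ", x$n_out, " ",
      x$unit, "s (", length(x$removed), " removed)\n", sep = "")
  invisible(x)
}

#' Marker QC: autosomes, call rate and minor allele frequency
#'
#' Retains autosomal markers whose call rate is at least
#' `params$marker_call_rate` and whose minor allele frequency (computed on
#' non-missing calls) is at least `params$maf_min`.
#'
#' @param cohort a `cohort`.
#' @param params a [qc_params()] set.
#' @return List with elements `cohort` and `report`.
#' @export
filter_markers <- function(cohort, params = qc_params()) {
  validate_cohort(cohort)
  n_in <- nrow(cohort$map)
  keep <- rep(TRUE, n_in)
  if (params$autosome_only) keep <- keep & cohort$map$autosomal
  cr <- colMeans(!is.na(cohort$geno))
  keep <- keep & cr >= params$marker_call_rate
  p_alt <- colMeans(cohort$geno, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  maf[is.nan(maf)] <- 0
  keep <- keep & maf >= params$maf_min & maf > 0
  if (!any(keep)) stop("no markers survive marker QC")
  out <- subset_cohort(cohort, markers = which(keep))
  list(cohort = out,
       report = qc_report("marker call rate/MAF/autosome",
                          cohort$map$id[!keep], n_in, sum(keep), "marker"))
}

#' Sample QC: call rate
#'
#' Removes samples with call rate strictly below `params$sample_call_rate`.
#' Run after [filter_markers()] (markers first, then samples).
#'
#' @inheritParams filter_markers
#' @return List with elements `cohort` and `report`.
#' @export
filter_samples <- function(cohort, params = qc_params()) {
  validate_cohort(cohort)
  cr <- rowMeans(!is.na(cohort$geno))
  keep <- cr >= params$sample_call_rate
  if (!any(keep)) stop("no samples survive sample QC")
  out <- subset_cohort(cohort, samples = which(keep))
  list(cohort = out,
       report = qc_report("sample call rate", cohort$samples$id[!keep],
                          nrow(cohort$samples), sum(keep), "sample"))
}

# Indicator matrices for fast pairwise statistics. Returns dense numeric
# matrices so the heavy lifting runs through BLAS.
geno_indicators <- function(geno) {
  g <- geno
  list(
    h0 = matrix(as.numeric(!is.na(g) & g == 0L), nrow(g)),
    h1 = matrix(as.numeric(!is.na(g) & g == 1L), nrow(g)),
    h2 = matrix(as.numeric(!is.na(g) & g == 2L), nrow(g)),
    m  = matrix(as.numeric(!is.na(g)), nrow(g))
  )
}

#' Pairwise identity-by-state matrix
#'
#' IBS between two samples is the mean over markers typed in both of the
#' shared-allele fraction (0, 0.5 or 1 per marker). Optional marker weights
#' support bootstrap resampling.
#'
#' @param cohort a `cohort`.
#' @param weights optional non-negative marker weights (e.g. bootstrap
#'   resampling counts); default all 1.
#' @return Symmetric samples x samples matrix with unit diagonal; entries are
#'   `NaN` for pairs with no co-typed marker.
#' @export
ibs_matrix <- function(cohort, weights = NULL) {
  validate_cohort(cohort)
  ind <- geno_indicators(cohort$geno)
  if (!is.null(weights)) {
    stopifnot(length(weights) == ncol(cohort$geno), all(weights >= 0))
    w <- as.numeric(weights)
    ind <- lapply(ind, function(h) h * rep(w, each = nrow(h)))
    # only one factor of each cross-product may carry the weights
    raw <- geno_indicators(cohort$geno)
    full <- tcrossprod(ind$h0, raw$h2) + tcrossprod(ind$h2, raw$h0)
    half <- tcrossprod(ind$h1, raw$h0 + raw$h2) + tcrossprod(ind$h0 + ind$h2, raw$h1)
    n <- tcrossprod(ind$m, raw$m)
  } else {
    full <- tcrossprod(ind$h0, ind$h2)
    full <- full + t(full)
    half <- tcrossprod(ind$h1, ind$h0 + ind$h2)
    half <- half + t(half)
    n <- tcrossprod(ind$m)
  }
  ibs <- 1 - (half * 0.5 + full) / n
  dimnames(ibs) <- list(cohort$samples$id, cohort$samples$id)
  ibs
}

#' Pairwise identity-by-state for one sample pair
#'
#' @param cohort a `cohort`.
#' @param a,b sample ids.
#' @return IBS fraction in `[0, 1]`; `NaN` (with a warning) if the pair has
#'   no co-typed marker.
#' @export
pairwise_ibs <- function(cohort, a, b) {
  validate_cohort(cohort)
  ia <- match(a, cohort$samples$id)
  ib <- match(b, cohort$samples$id)
  if (is.na(ia) || is.na(ib)) stop("unknown sample id")
  ga <- cohort$geno[ia, ]; gb <- cohort$geno[ib, ]
  ok <- !is.na(ga) & !is.na(gb)
  if (!any(ok)) {
    warning("samples ", a, " and ", b, " share no typed markers")
    return(NaN)
  }
  mean(1 - abs(ga[ok] - gb[ok]) / 2)
}

#' Discordant-homozygote (Mendelian error) count for a sample pair
#'
#' Number of markers at which one sample is homozygous for allele 1 and the
#' other homozygous for allele 2. Near zero for parent-offspring pairs.
#'
#' @inheritParams pairwise_ibs
#' @return Integer count.
#' @export
discordant_homozygotes <- function(cohort, a, b) {
  validate_cohort(cohort)
  ia <- match(a, cohort$samples$id)
  ib <- match(b, cohort$samples$id)
  if (is.na(ia) || is.na(ib)) stop("unknown sample id")
  ga <- cohort$geno[ia, ]; gb <- cohort$geno[ib, ]
  ok <- !is.na(ga) & !is.na(gb)
  sum((ga[ok] == 0L & gb[ok] == 2L) | (ga[ok] == 2L & gb[ok] == 0L))
}

#' All pairwise discordant-homozygote counts
#'
#' @param cohort a `cohort`.
#' @return Symmetric integer matrix of ME counts.
#' @export
me_matrix <- function(cohort) {
  validate_cohort(cohort)
  ind <- geno_indicators(cohort$geno)
  me <- tcrossprod(ind$h0, ind$h2)
  me <- me + t(me)
  dimnames(me) <- list(cohort$samples$id, cohort$samples$id)
  me
}

#' Detect duplicated individuals by identity-by-state
#'
#' @param cohort a `cohort`.
#' @param params a [qc_params()] set (`duplicate_ibs` threshold, strict `>`).
#' @return data.frame of flagged pairs (`a`, `b`, `ibs`), `a < b`
#'   lexicographically.
#' @export
find_duplicates <- function(cohort, params = qc_params()) {
  ibs <- ibs_matrix(cohort)
  n <- nrow(ibs)
  out <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (!is.nan(ibs[i, j]) && ibs[i, j] > params$duplicate_ibs) {
          pr <- sort(c(rownames(ibs)[i], rownames(ibs)[j]))
          out[[length(out) + 1L]] <- data.frame(a = pr[1L], b = pr[2L],
                                                ibs = ibs[i, j],
                                                stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(a = character(0), b = character(0), ibs = numeric(0)))
  }
  do.call(rbind, out)
}

# collapse duplicate clusters, keeping the lexicographically first id of each
drop_duplicates <- function(cohort, dup_pairs) {
  if (nrow(dup_pairs) == 0L) {
    return(list(cohort = cohort,
                report = qc_report("duplicate removal", character(0),
                                   nrow(cohort$samples), nrow(cohort$samples),
                                   "sample")))
  }
  # union-find so that clones of clones collapse to a single retained sample
  ids <- cohort$samples$id
  parent <- stats::setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_len(nrow(dup_pairs))) {
    ra <- find(dup_pairs$a[k]); rb <- find(dup_pairs$b[k])
    if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
  }
  roots <- vapply(ids, find, "")
  drop <- ids[roots != ids]
  keep <- setdiff(ids, drop)
  list(cohort = subset_cohort(cohort, samples = keep),
       report = qc_report("duplicate removal", drop, length(ids),
                          length(keep), "sample"))
}

#' Prune close relatives by discordant-homozygote count
#'
#' A pair is "related" if its ME count is strictly below the (possibly
#' marker-count-rescaled) threshold. Pruning is greedy: while related pairs
#' remain, remove the sample participating in the most such pairs, breaking
#' ties by lower call rate and then by lexicographically later id.
#'
#' @param cohort a `cohort`.
#' @param params a [qc_params()] set.
#' @return List with elements `cohort` and `report`.
#' @export
relatedness_prune <- function(cohort, params = qc_params()) {
  validate_cohort(cohort)
  thr <- params$me_max
  if (params$me_scale) thr <- thr * ncol(cohort$geno) / params$me_ref_markers
  me <- me_matrix(cohort)
  diag(me) <- Inf
  rel <- me < thr
  cr <- rowMeans(!is.na(cohort$geno))
  names(cr) <- cohort$samples$id
  removed <- character(0)
  active <- rownames(me)
  while (TRUE) {
    deg <- rowSums(rel[active, active, drop = FALSE])
    if (!any(deg > 0)) break
    cand <- active[deg == max(deg)]
    if (length(cand) > 1L) {
      cand <- cand[cr[cand] == min(cr[cand])]
      cand <- sort(cand, decreasing = TRUE)
    }
    victim <- cand[1L]
    removed <- c(removed, victim)
    active <- setdiff(active, victim)
  }
  list(cohort = subset_cohort(cohort, samples = active),
       report = qc_report("relatedness pruning", removed,
                          nrow(cohort$samples), length(active), "sample"))
}

#' Full QC pipeline
#'
#' Applies, in order: marker QC, sample call-rate QC, duplicate removal,
#' relatedness pruning. The composition is idempotent.
#'
#' @param cohort a `cohort`.
#' @param params a [qc_params()] set.
#' @return List with elements `cohort` and `reports` (one [qc_report] per
#'   stage).
#' @export
run_qc <- function(cohort, params = qc_params()) {
  s1 <- filter_markers(cohort, params)
  s2 <- filter_samples(s1$cohort, params)
  dup <- find_duplicates(s2$cohort, params)
  s3 <- drop_duplicates(s2$cohort, dup)
  s4 <- relatedness_prune(s3$cohort, params)
  list(cohort = s4$cohort,
       reports = list(markers = s1$report, samples = s2$report,
                      duplicates = s3$report, relatedness = s4$report))
}

#' Serialize QC reports as JSON
#'
#' @param reports the `reports` element of [run_qc()] output.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(reports, path) {
  x <- lapply(reports, function(r) {
    list(rule = r$rule, n_in = r$n_in, n_out = r$n_out,
         removed = as.list(r$removed))
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
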