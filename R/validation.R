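#' @title Validation studies
#' @name validation
#' @description
#' Fixed simulation designs that exercise each stage of the pipeline against
#' ground truth. Each function runs one study end-to-end and returns the
#' summary statistics it measures. The designs (population sizes, founder
#' pool sizes, marker densities, genome sizes) are part of the package's
#' validation protocol: they are chosen to represent closed breed-scale
#' populations on array-density data and are documented in the methods
#' vignette.
NULL

#' Classifier check against the published Italian-breed table
#'
#' Re-derives the breed status of every population in
#' [italian_breed_metrics()] that has a printed status of its own (i.e. was
#' not assessed jointly with a sibling population) from its printed metrics,
#' monophyly flag and sample size, and compares with the printed status.
#'
#' @return List with `n_rows`, `n_match` and `accuracy` (fraction matched).
#' @export
validate_classifier <- function() {
  tab <- italian_breed_metrics()
  tab <- tab[!is.na(tab$status) & is.na(tab$combined_with), ]
  pred <- vapply(seq_len(nrow(tab)), function(i) {
    classify_status(tab$n[i], tab$f[i], tab$lnh_mb[i], tab$shared_lnh_mb[i],
                    tab$decay[i], tab$monophyletic[i])$status
  }, "")
  truth <- ifelse(tab$status == "Insufficient", "Insufficient", tab$status)
  list(n_rows = nrow(tab), n_match = sum(pred == truth),
       accuracy = mean(pred == truth),
       mismatches = tab$breed[pred != truth])
}

#' Neighbor-joining consistency on additive distances
#'
#' Draws random trees, converts each to its additive (cophenetic) distance
#' matrix and checks that [neighbor_joining()] recovers the generating
#' topology exactly.
#'
#' @param n_trees number of random trees (default 50).
#' @param leaves range of leaf counts (default 6 to 12).
#' @param seed random seed.
#' @return List with `n_trees`, `n_recovered`, `recovery_rate`.
#' @export
validate_nj_recovery <- function(n_trees = 50L, leaves = c(6L, 12L), seed = 1L) {
  set.seed(seed)
  ok <- logical(n_trees)
  for (i in seq_len(n_trees)) {
    n <- sample(seq(leaves[1L], leaves[2L]), 1L)
    tr <- ape::rtree(n)
    tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 1)
    d <- ape::cophenetic.phylo(tr)
    rec <- neighbor_joining(d[tr$tip.label, tr$tip.label])
    ok[i] <- ape::dist.topo(ape::unroot(tr), ape::unroot(rec)) == 0
  }
  list(n_trees = n_trees, n_recovered = sum(ok), recovery_rate = mean(ok))
}

#' Bootstrap monophyly study
#'
#' Simulates six breeds plus an outgroup, all founded from one ancestral
#' pool 100 generations ago (a star radiation, so every between-breed split
#' is 100 generations deep), on an array of 20k SNPs, then measures
#' per-breed monophyly support over 100 bootstrap replicates — once with the
#' true labels and once with labels randomly permuted across dogs.
#'
#' @param seed random seed.
#' @param replicates bootstrap replicates (default 100).
#' @param n_markers marker count (default 20000).
#' @return List with `min_support` (over the six true breeds),
#'   `supports`, and `max_permuted_support`.
#' @export
validate_bootstrap_monophyly <- function(seed = 1L, replicates = 100L,
                                         n_markers = 20000L) {
  pops <- stats::setNames(rep(12L, 7L), c(paste0("B", 1:6), "OG"))
  cfg <- breed_history(
    chrom_lengths = rep(1e8, 10), n_markers = n_markers,
    n_founder_haps = 200L, populations = pops, generations = 100,
    sample_sizes = stats::setNames(c(rep(10L, 6L), 2L), names(pops)),
    seed = derive_seed(seed, "simulate")
  )
  sim <- simulate_cohort(cfg)
  pp <- phylo_params(replicates = replicates, outgroup = "OG",
                     seed = derive_seed(seed, "phylo"))
  bp <- bootstrap_consensus(sim$cohort, pp)
  sup <- breed_monophyly(bp$support)

  perm <- sim$cohort
  set.seed(derive_seed(seed, "subsample"))
  non_og <- perm$samples$breed != "OG"
  perm$samples$breed[non_og] <- sample(perm$samples$breed[non_og])
  bp2 <- bootstrap_consensus(perm, pp)
  sup2 <- breed_monophyly(bp2$support)

  list(min_support = min(sup), supports = sup,
       max_permuted_support = max(sup2))
}

#' Identity-by-descent truth-recovery study
#'
#' One population of 10 dogs with recent shared ancestry (founded 8
#' generations ago from a 40-haplotype pool) at 50 SNPs/Mb. Shared segments
#' of at least 2 Mb detected from the truth-phase haplotypes are compared
#' with the simulator's exact IBD: recall is the fraction of true IBD length
#' (segments >= 2 Mb) overlapped by detections, precision the fraction of
#' detected length overlapping true IBD of any length.
#'
#' @param seed random seed.
#' @return List with `recall`, `precision`, `true_mb`, `detected_mb`.
#' @export
validate_ibd_recovery <- function(seed = 1L) {
  cfg <- breed_history(
    chrom_lengths = rep(5e7, 5), n_markers = 12500L,  # 50 SNPs/Mb
    n_founder_haps = 40L, populations = c(P = 10L), generations = 8,
    seed = derive_seed(seed, "simulate")
  )
  sim <- simulate_cohort(cfg)
  sp <- sharing_params(min_len = 2e6)
  ids <- sim$cohort$samples$id
  tp <- 0; truth_len <- 0; det_len <- 0
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq(i + 1L, length(ids))) {
      tru_all <- true_pair_ibd(sim$truth, ids[i], ids[j], min_len = 0)
      tru_big <- tru_all[tru_all$length >= 2e6, , drop = FALSE]
      det <- detect_shared_segments(sim$phased, ids[i], ids[j], sp)
      for (ch in unique(sim$cohort$map$chrom)) {
        tb <- tru_big[tru_big$chrom == ch, , drop = FALSE]
        ta <- tru_all[tru_all$chrom == ch, , drop = FALSE]
        dd <- det[det$chrom == ch, , drop = FALSE]
        ub <- interval_union(tb$start, tb$end)
        ua <- interval_union(ta$start, ta$end)
        ud <- interval_union(dd$start, dd$end)
        truth_len <- truth_len + sum(if (nrow(ub)) ub[, 2] - ub[, 1] + 1 else 0)
        det_len <- det_len + sum(if (nrow(ud)) ud[, 2] - ud[, 1] + 1 else 0)
        tp <- tp + interval_intersect_length(ub, ud)
      }
    }
  }
  # precision against IBD of any length (union of all true segments)
  tp_prec <- 0
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq(i + 1L, length(ids))) {
      tru_all <- true_pair_ibd(sim$truth, ids[i], ids[j], min_len = 0)
      det <- detect_shared_segments(sim$phased, ids[i], ids[j], sp)
      for (ch in unique(sim$cohort$map$chrom)) {
        ta <- tru_all[tru_all$chrom == ch, , drop = FALSE]
        dd <- det[det$chrom == ch, , drop = FALSE]
        tp_prec <- tp_prec + interval_intersect_length(
          interval_union(ta$start, ta$end), interval_union(dd$start, dd$end)
        )
      }
    }
  }
  list(recall = tp / truth_len, precision = tp_prec / det_len,
       true_mb = truth_len / 1e6, detected_mb = det_len / 1e6)
}

#' Divergence-dating recovery study
#'
#' For each split depth, two breeds of 25 (20 sampled) are founded `g`
#' generations ago from a shared 100-haplotype ancestral pool on a 2,000 cM
#' genome (20 chromosomes, 30 SNPs/Mb), giving every cross-breed dog pair
#' detectable sharing. Cross-breed and within-breed medians of pair sharing
#' feed [divergence_time()]; the study reports the estimated generations per
#' split depth, averaged over seeds. Estimates are expected to increase
#' strictly with the true depth; their absolute scale is compressed because
#' the 100/(2L) relation applies to single-segment lengths while the median
#' aggregates per-pair sums (see the methods vignette).
#'
#' @param gens true split depths (default `c(5, 25, 50)`).
#' @param seeds integer vector of seeds (default 3 seeds).
#' @param n_markers marker count (default 60000).
#' @return data.frame with columns `g_true`, `g_hat` (mean over seeds),
#'   `rel_err`, plus one row per seed in the `per_seed` attribute.
#' @export
validate_dating <- function(gens = c(5, 25, 50), seeds = 1:3,
                            n_markers = 60000L) {
  per <- list()
  for (g in gens) {
    for (s in seeds) {
      cfg <- breed_history(
        chrom_lengths = rep(1e8, 20), n_markers = n_markers,
        n_founder_haps = 100L, populations = c(A = 25L, B = 25L),
        generations = g, sample_sizes = c(A = 20L, B = 20L),
        clades = c(A = "cladeA", B = "cladeB"),
        seed = derive_seed(s, "simulate") + g
      )
      sim <- simulate_cohort(cfg)
      sp <- sharing_params(min_len = 1e6)
      sums_cross <- all_pair_sharing(sim$phased, params = sp)
      wp <- within_breed_pairs(sim$phased$samples)
      sums_within <- all_pair_sharing(sim$phased, wp, params = sp)
      med_ab <- stats::median(sums_cross$bp)
      breed_of <- stats::setNames(sim$phased$samples$breed, sim$phased$samples$id)
      med_aa <- stats::median(sums_within$bp[breed_of[sums_within$a] == "A"])
      med_bb <- stats::median(sums_within$bp[breed_of[sums_within$a] == "B"])
      dt <- suppressMessages(divergence_time(med_ab, med_aa, med_bb))
      per[[length(per) + 1L]] <- data.frame(
        g_true = g, seed = s, g_hat = dt$generations,
        median_ab_mb = med_ab / 1e6,
        median_within_mb = min(med_aa, med_bb) / 1e6
      )
    }
  }
  per <- do.call(rbind, per)
  out <- do.call(rbind, lapply(split(per, per$g_true), function(d) {
    data.frame(g_true = d$g_true[1L], g_hat = mean(d$g_hat, na.rm = TRUE),
               rel_err = mean(d$g_hat, na.rm = TRUE) / d$g_true[1L] - 1)
  }))
  rownames(out) <- NULL
  attr(out, "per_seed") <- per
  out
}

#' Null calibration of the cross-clade significance rule
#'
#' Eighteen breeds in six clades, with no admixture: clade ancestors split
#' from a common 250-haplotype pool 40 generations ago and breeds within a
#' clade 20 generations ago. With the empirical 95th-percentile rule,
#' close to 5 percent of the cross-clade breed pairs should be flagged by
#' construction.
#'
#' @param seed random seed.
#' @param n_markers marker count (default 25000; 50 SNPs/Mb).
#' @return List with `n_pairs`, `n_flagged`, `flag_fraction`, `threshold_bp`.
#' @export
validate_null_calibration <- function(seed = 1L, n_markers = 25000L) {
  clades <- paste0("cl", 1:6)
  anc <- stats::setNames(rep(30L, 6L), paste0("anc_", clades))
  events <- list()
  breeds <- character(0)
  breed_clade <- character(0)
  for (ci in seq_along(clades)) {
    for (k in 1:3) {
      b <- sprintf("%s_b%d", clades[ci], k)
      breeds <- c(breeds, b)
      breed_clade[b] <- clades[ci]
      events[[length(events) + 1L]] <-
        list(type = "split", gen = 20, source = names(anc)[ci], target = b,
             size = 15L)
    }
  }
  cfg <- breed_history(
    chrom_lengths = rep(1e8, 5), n_markers = n_markers,
    n_founder_haps = 250L, populations = anc, generations = 40,
    events = events,
    sample_sizes = stats::setNames(rep(8L, length(breeds)), breeds),
    clades = breed_clade,
    seed = derive_seed(seed, "simulate")
  )
  sim <- simulate_cohort(cfg)
  sums <- all_pair_sharing(sim$phased, params = sharing_params())
  stats_tab <- breed_pair_medians(sums, sim$phased$samples)
  thr <- significance_threshold(stats_tab)
  flagged <- flag_significant(stats_tab, thr)
  list(n_pairs = nrow(stats_tab), n_flagged = sum(flagged$significant),
       flag_fraction = mean(flagged$significant), threshold_bp = thr)
}

#' Inbreeding-coefficient recovery study
#'
#' Single populations simulated to three target autozygosity levels
#' (outbred founders; 25 diploids for 5 generations; 25 diploids for 14
#' generations), ten seeds each. The method-of-moments F (with founder
#' allele frequencies as the reference) is compared with the simulator's
#' exact mean autozygosity.
#'
#' @param seeds integer vector of seeds (default 10 seeds).
#' @return data.frame with one row per level: `target`, `truth`
#'   (mean true autozygosity), `f_hat` (mean F), `abs_err`.
#' @export
validate_f_recovery <- function(seeds = 1:10) {
  levels <- list(
    list(target = 0, N = 50L, gens = 0),
    list(target = 0.10, N = 25L, gens = 5),
    list(target = 0.25, N = 25L, gens = 14)
  )
  rows <- list()
  for (lv in levels) {
    truths <- fhats <- numeric(length(seeds))
    for (si in seq_along(seeds)) {
      cfg <- breed_history(
        chrom_lengths = rep(1e8, 3), n_markers = 6000L,
        n_founder_haps = 200L, populations = stats::setNames(lv$N, "P"),
        generations = lv$gens,
        sample_sizes = c(P = min(lv$N, 25L)),
        seed = derive_seed(seeds[si], "simulate") + lv$gens
      )
      sim <- simulate_cohort(cfg)
      ids <- sim$cohort$samples$id
      truths[si] <- mean(vapply(ids, function(s) true_autozygosity(sim$truth, s),
                                numeric(1)))
      fhats[si] <- mean(inbreeding_f(sim$cohort, freq = sim$truth$founder_freq))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      target = lv$target, truth = mean(truths), f_hat = mean(fhats),
      abs_err = abs(mean(fhats) - mean(truths))
    )
  }
  do.call(rbind, rows)
}

#' Bundled smoke-test pipeline configuration
#'
#' Six simulated breeds of ten sampled dogs each (plus a small outgroup),
#' 5k SNPs, splits 30 generations deep, with 30 bootstrap replicates — a
#' complete but fast end-to-end exercise of the pipeline.
#'
#' @param out_dir output directory.
#' @param seed global pipeline seed.
#' @return A [pipeline_config()].
#' @export
smoke_pipeline_config <- function(out_dir = tempfile("breedscape_smoke_"),
                                  seed = 1L) {
  pops <- stats::setNames(rep(12L, 7L), c(paste0("B", 1:6), "OG"))
  sim <- breed_history(
    chrom_lengths = rep(1e8, 5), n_markers = 5000L, n_founder_haps = 150L,
    populations = pops, generations = 30,
    sample_sizes = stats::setNames(c(rep(10L, 6L), 2L), names(pops)),
    clades = stats::setNames(c("c1", "c1", "c2", "c2", "c3", "c3", "og"),
                             names(pops)),
    missing_rate = 0.01
  )
  pipeline_config(
    simulation = sim,
    phylo = phylo_params(replicates = 30L, outgroup = "OG"),
    roh = roh_params(min_snps = 30L),
    out_dir = out_dir, seed = seed
  )
}
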