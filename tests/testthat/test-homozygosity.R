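# small-window parameters used for hand-checkable fixtures
toy_roh <- function(min_snps = 5) {
  roh_params(window_snps = 5, window_max_het = 1, window_max_missing = 1,
             min_snps = min_snps, min_kb = 0.001, max_gap_kb = 1e6,
             shared_min_kb = 0.001)
}

test_that("ROH calling handles the homozygous and heterozygous extremes", {
  g_hom <- matrix(0L, 1, 300)
  co <- mk_cohort(g_hom, spacing = 1e4)
  seg <- detect_roh(co, "s01", roh_params(min_snps = 100, min_kb = 100))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start, 1e4)
  expect_equal(seg$end, 300e4)
  expect_equal(seg$n_snps, 300)
  g_het <- matrix(1L, 1, 300)
  co2 <- mk_cohort(g_het, spacing = 1e4)
  expect_equal(nrow(detect_roh(co2, "s01", roh_params(min_snps = 50, min_kb = 10))), 0)
})

test_that("a planted homozygous tract with one het is recovered as brute force dictates", {
  set.seed(4)
  L <- 2000
  g <- rbinom(L, 2, 0.5)
  het_free <- rep(c(0L, 2L), length.out = 150)
  g[901:1050] <- het_free
  g[975] <- 1L                         # single het inside the tract
  pos <- sort(sample.int(4e7, L))
  co <- mk_cohort(matrix(g, 1), pos = pos)
  p <- roh_params(window_snps = 50, min_snps = 100, min_kb = 100)
  got <- detect_roh(co, "s01", p)
  bf <- bf_roh(g, pos, p)
  expect_equal(nrow(got), nrow(bf))
  expect_equal(got$start, bf$start)
  expect_equal(got$end, bf$end)
  expect_equal(got$n_snps, bf$n_snps)
  expect_equal(nrow(got), 1)
  expect_true(got$start >= pos[880] && got$end <= pos[1070])
})

test_that("ROH detection equals brute force across random fixtures", {
  for (s in 1:8) {
    set.seed(600 + s)
    L <- 600
    # mixture genome: noisy stretches and homozygous stretches
    g <- rbinom(L, 2, 0.5)
    tr_start <- sample(50:400, 1)
    tr_len <- sample(120:200, 1)
    g[tr_start:(tr_start + tr_len)] <- sample(c(0L, 2L), tr_len + 1, TRUE,
                                              prob = c(0.5, 0.5))
    g[sample(L, 20)] <- NA
    pos <- sort(sample.int(2e7, L))
    p <- roh_params(window_snps = 25, window_max_het = 1, window_max_missing = 2,
                    min_snps = 40, min_kb = 50, max_gap_kb = 500)
    co <- mk_cohort(matrix(g, 1), pos = pos)
    got <- detect_roh(co, "s01", p)
    bf <- bf_roh(g, pos, p)
    expect_equal(got[, c("start", "end", "n_snps")],
                 bf[, c("start", "end", "n_snps")],
                 ignore_attr = TRUE)
  }
})

test_that("single-dog LnH sums segment lengths in Mb", {
  expect_equal(single_dog_lnh(data.frame(start = numeric(0), end = numeric(0))), 0)
  segs <- data.frame(start = c(1, 3e7), end = c(1e7, 4e7 - 1))
  expect_equal(single_dog_lnh(segs), 20)
})

test_that("LnH recovers the simulator's autozygous fraction", {
  sim <- simulate_cohort(breed_history(
    chrom_lengths = rep(1e8, 4), n_markers = 20000, n_founder_haps = 200,
    populations = c(P = 25), generations = 18, sample_sizes = c(P = 12),
    seed = 77L
  ))
  p <- roh_params(min_snps = 50)           # 50 SNPs/Mb panel: 1 Mb minimum
  ids <- sim$cohort$samples$id
  lnh <- vapply(ids, function(d) single_dog_lnh(detect_roh(sim$cohort, d, p)),
                numeric(1))
  truth <- vapply(ids, function(d) true_autozygosity(sim$truth, d), numeric(1))
  genome_mb <- sum(sim$truth$chrom_lengths) / 1e6
  expect_gt(mean(truth), 0.2)              # the design is strongly inbred
  expect_lt(abs(mean(lnh) - mean(truth) * genome_mb) / (mean(truth) * genome_mb),
            0.15)
})

test_that("shared LnH of clones equals the single-dog LnH", {
  g <- rep(c(0L, 2L), length.out = 400)   # het-free homozygous genome
  co <- mk_cohort(matrix(rep(g, each = 6), 6), spacing = 5e4)
  p <- roh_params(window_snps = 25, min_snps = 30, min_kb = 100,
                  shared_min_kb = 100)
  lnh1 <- single_dog_lnh(detect_roh(co, "s01", p))
  expect_gt(lnh1, 0)
  expect_equal(shared_lnh(co, "pop", params = p), lnh1)
  # residual heterozygotes sit inside single-dog ROH but break the shared
  # same-allele intervals, so sharing can only fall slightly below
  set.seed(9)
  g2 <- g
  g2[sample(400, 8)] <- 1L
  co2 <- mk_cohort(matrix(rep(g2, each = 6), 6), spacing = 5e4)
  lnh2 <- single_dog_lnh(detect_roh(co2, "s01", p))
  sh2 <- shared_lnh(co2, "pop", params = p)
  expect_lte(sh2, lnh2)
  expect_gt(sh2, 0.9 * lnh2)
})

test_that("shared LnH counts only allele-matching overlap, as hand computed", {
  # 60 markers at 100 kb spacing; all three dogs fully homozygous (one ROH
  # each); dogs 1-2 share allele A on markers 1..40, dog 3 carries B there;
  # all three match on markers 41..60
  g1 <- c(rep(0L, 40), rep(0L, 20))
  g2 <- c(rep(0L, 40), rep(0L, 20))
  g3 <- c(rep(2L, 40), rep(0L, 20))
  co <- mk_cohort(rbind(g1, g2, g3), spacing = 1e5)
  p <- toy_roh(min_snps = 10)
  segs <- lapply(co$samples$id, function(d) detect_roh(co, d, p))
  expect_true(all(vapply(segs, nrow, integer(1)) == 1))
  sh12 <- shared_lnh(co, "pop", dogs = c("s01", "s02"), params = p)
  sh123 <- shared_lnh(co, "pop", dogs = c("s01", "s02", "s03"), params = p)
  # dogs 1-2 share the whole span (6.0 Mb papered over 60 markers minus the
  # first marker's offset: 100 kb..6,000 kb inclusive)
  expect_equal(sh12, (6e6 - 1e5 + 1) / 1e6)
  # adding dog 3 restricts the match to markers 41..60
  expect_equal(sh123, (6e6 - 41e5 + 1) / 1e6)
})

test_that("shared LnH requires five dogs and decays monotonically with k", {
  co <- make_random_cohort(4, 100, seed = 21, n_breeds = 1)
  expect_message(v <- shared_lnh(co, "br1"), "n = 4")
  expect_true(is.na(v))
  sim <- simulate_cohort(breed_history(
    chrom_lengths = rep(5e7, 3), n_markers = 7500, n_founder_haps = 60,
    populations = c(P = 15), generations = 12, sample_sizes = c(P = 8),
    seed = 31L
  ))
  p <- roh_params(min_snps = 50)
  dc <- decay_rate(sim$cohort, "P", params = p, seed = 2)
  expect_false(is.na(dc$rate))
  expect_true(all(diff(dc$profile$S_k) <= 1e-9))
  expect_gte(dc$rate, 0)
})

test_that("the decay fit matches closed forms on synthetic profiles", {
  # halving per added dog: ln S_k = a - k ln 2
  ks <- 2:10
  Sk <- 100 * 0.5^(ks - 2)
  fit <- stats::lm(log(Sk) ~ ks)
  expect_equal(unname(-coef(fit)[2]), log(2))
  # independent closed-form least squares on a 5-point fixture
  ks5 <- 2:6
  S5 <- c(90, 60, 35, 30, 22)
  fit5 <- stats::lm(log(S5) ~ ks5)
  x <- ks5 - mean(ks5); y <- log(S5) - mean(log(S5))
  expect_equal(unname(coef(fit5)[2]), sum(x * y) / sum(x * x))
})

test_that("a breed of clones has decay rate zero", {
  set.seed(5)
  g <- rep(c(0L, 2L), length.out = 300)
  co <- mk_cohort(matrix(rep(g, each = 6), 6), spacing = 5e4)
  p <- roh_params(window_snps = 25, min_snps = 30, min_kb = 100,
                  shared_min_kb = 100, decay_orderings = 3)
  dc <- decay_rate(co, "pop", params = p, seed = 1)
  expect_equal(dc$rate, 0, tolerance = 1e-12)
})

test_that("method-of-moments F hits its closed-form anchor points", {
  # fully homozygous sample -> F = 1 regardless of frequencies
  g_all <- rbind(rep(0L, 10), c(rep(1L, 5), rep(0L, 5)), rep(1L, 10))
  co <- mk_cohort(g_all)
  f <- inbreeding_f(co, freq = rep(0.5, 10))
  expect_equal(unname(f["s01"]), 1)
  # expected het count = 5 at p = 0.5 over 10 markers: observed 5 het -> F = 0
  expect_equal(unname(f["s02"]), 0)
  # all het with E_het = 5: F = (0 - 5)/(10 - 5) = -1
  expect_equal(unname(f["s03"]), -1)
})

test_that("status classification reproduces the published worked examples", {
  expect_equal(classify_status(9, 0.220, 1843.258, 382.935, 0.450, TRUE)$status,
               "Breed")
  expect_equal(classify_status(15, 0.213, 1912.347, 361.279, 0.299, FALSE)$status,
               "Variety")
  expect_equal(classify_status(14, 0.092, 1856.336, 385.056, 0.665, TRUE)$status,
               "NotBreed")
  expect_equal(classify_status(2, 0.026, 1815.659, NA, NA, FALSE)$status,
               "Insufficient")
  # absent metrics rescale the 3-of-4 rule: 3 available -> all 3 required
  ok3 <- classify_status(6, 0.318, 1897.332, NA, 0.358, TRUE)
  expect_equal(ok3$status, "Breed")
  bad3 <- classify_status(6, 0.318, 1897.332, NA, 0.700, TRUE)
  expect_equal(bad3$status, "NotBreed")
})

test_that("breed_metrics assembles a coherent per-breed table", {
  sim <- simulate_cohort(breed_history(
    chrom_lengths = rep(5e7, 3), n_markers = 7500, n_founder_haps = 60,
    populations = c(A = 10, B = 10), generations = 15,
    sample_sizes = c(A = 6, B = 6), seed = 41L
  ))
  tab <- breed_metrics(sim$cohort, monophyly = c(A = TRUE, B = FALSE),
                       params = roh_params(min_snps = 50))
  expect_equal(sort(tab$breed), c("A", "B"))
  expect_equal(tab$n, c(6, 6))
  expect_true(all(tab$lnh_mb >= 0))
  expect_true(all(tab$status %in% c("Breed", "Variety", "NotBreed", "Insufficient")))
})
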