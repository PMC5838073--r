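test_that("same config and seed reproduce identical cohort and truth", {
  cfg <- breed_history(chrom_lengths = rep(3e7, 2), n_markers = 400,
                       populations = c(A = 8, B = 8), generations = 10,
                       missing_rate = 0.02, seed = 5L)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort$geno, s2$cohort$geno)
  expect_identical(s1$phased$hap, s2$phased$hap)
  expect_identical(s1$truth$mosaics, s2$truth$mosaics)
})

test_that("mosaics tile every chromosome exactly", {
  cfg <- breed_history(chrom_lengths = c(chrA = 3e7, chrB = 5e7), n_markers = 200,
                       populations = c(A = 10), generations = 15, seed = 9L)
  sim <- simulate_cohort(cfg)
  for (m in sim$truth$mosaics) {
    for (h in m) {
      for (ci in seq_along(h)) {
        ends <- h[[ci]]$end
        expect_true(all(diff(ends) > 0))
        expect_equal(ends[length(ends)], unname(cfg$chrom_lengths[ci]))
        expect_equal(length(ends), length(h[[ci]]$fnd))
      }
    }
  }
})

test_that("a zero-generation split leaves cross- and within-population sharing equal", {
  cfg <- breed_history(
    chrom_lengths = rep(5e7, 2), n_markers = 300, n_founder_haps = 30,
    populations = c(anc = 20), generations = 1,
    events = list(list(type = "split", gen = 0, source = "anc", target = "B",
                       size = 10)),
    sample_sizes = c(anc = 10, B = 10), seed = 31L
  )
  sim <- simulate_cohort(cfg)
  expect_equal(sim$truth$split_gens["anc", "B"], 0)
  ids_a <- grep("^anc", names(sim$truth$mosaics), value = TRUE)
  ids_b <- grep("^B", names(sim$truth$mosaics), value = TRUE)
  pair_sum <- function(x, y) {
    s <- true_pair_ibd(sim$truth, x, y)
    sum(s$length)
  }
  within <- c(
    mapply(pair_sum, ids_a[1:5], ids_a[6:10]),
    mapply(pair_sum, ids_b[1:5], ids_b[6:10])
  )
  cross <- mapply(pair_sum, ids_a, ids_b)
  # both kinds of pair draw parents from the same generation-1 pool
  expect_gt(mean(cross), 0)
  expect_lt(abs(mean(cross) - mean(within)) / mean(within), 0.75)
})

test_that("mean autozygosity matches the pedigree expectation 1-(1-1/(2N))^g", {
  N <- 100L; g <- 50
  vals <- vapply(1:20, function(s) {
    cfg <- breed_history(chrom_lengths = rep(5e7, 2), n_markers = 10,
                         populations = c(P = N), generations = g,
                         sample_sizes = c(P = 30L), seed = 100L + s)
    sim <- simulate_cohort(cfg)
    mean(vapply(names(sim$truth$mosaics),
                function(id) true_autozygosity(sim$truth, id), numeric(1)))
  }, numeric(1))
  expected <- 1 - (1 - 1 / (2 * N))^g
  expect_lt(abs(mean(vals) - expected), 0.03)
})

test_that("true_pair_ibd matches a brute-force scan over mosaic breakpoints", {
  # 3-chromosome toy with hand-written mosaics
  lens <- c(c1 = 100, c2 = 80, c3 = 60)
  mos <- list(
    d1 = list(
      list(c1 = list(end = c(40, 100), fnd = c(1L, 2L)),
           c2 = list(end = 80, fnd = 3L),
           c3 = list(end = c(20, 60), fnd = c(4L, 5L))),
      list(c1 = list(end = 100, fnd = 6L),
           c2 = list(end = c(30, 80), fnd = c(7L, 3L)),
           c3 = list(end = 60, fnd = 8L))
    ),
    d2 = list(
      list(c1 = list(end = c(50, 100), fnd = c(1L, 9L)),
           c2 = list(end = 80, fnd = 7L),
           c3 = list(end = 60, fnd = 5L)),
      list(c1 = list(end = 100, fnd = 2L),
           c2 = list(end = c(60, 80), fnd = c(3L, 1L)),
           c3 = list(end = 60, fnd = 4L))
    )
  )
  truth <- mk_truth(mos, lens)
  got <- true_pair_ibd(truth, "d1", "d2")
  # brute force: per bp-unit grid comparison of founder ids
  fnd_at <- function(h, x) h$fnd[findInterval(x, h$end, left.open = TRUE) + 1]
  bf <- 0
  for (ci in names(lens)) {
    xs <- seq(0.5, lens[[ci]] - 0.5, by = 1)
    for (i in 1:2) {
      for (j in 1:2) {
        bf <- bf + sum(fnd_at(mos$d1[[i]][[ci]], xs) == fnd_at(mos$d2[[j]][[ci]], xs))
      }
    }
  }
  expect_equal(sum(got$length), bf)
  # symmetry up to pairing relabel
  rev <- true_pair_ibd(truth, "d2", "d1")
  expect_equal(sum(rev$length), sum(got$length))
  expect_setequal(
    paste(got$chrom, got$start, got$end),
    paste(rev$chrom, rev$start, rev$end)
  )
})

test_that("twins share everything; disjoint founder pools share nothing", {
  lens <- c(c1 = 100)
  a <- list(
    list(c1 = list(end = c(30, 100), fnd = c(1L, 2L))),
    list(c1 = list(end = 100, fnd = 3L))
  )
  b_disjoint <- list(
    list(c1 = list(end = 100, fnd = 10L)),
    list(c1 = list(end = c(50, 100), fnd = c(11L, 12L)))
  )
  truth <- mk_truth(list(d1 = a, d2 = a, d3 = b_disjoint), lens)
  twins <- true_pair_ibd(truth, "d1", "d2")
  # identical pairings cover the whole chromosome
  cov <- twins[twins$pairing %in% c("11", "22"), ]
  expect_equal(sum(cov$length), 2 * 100)
  expect_equal(nrow(true_pair_ibd(truth, "d1", "d3")), 0)
})

test_that("inconsistent event graphs are rejected", {
  expect_error(
    simulate_cohort(breed_history(
      populations = c(A = 5), generations = 10, n_markers = 50,
      events = list(
        list(type = "split", gen = 8, source = "A", target = "B", size = 5),
        list(type = "split", gen = 9, source = "B", target = "C", size = 5)
      )
    )),
    "unknown source|does not exist"
  )
  expect_error(
    breed_history(populations = c(A = 5), generations = 5,
                  events = list(list(type = "admixture", gen = 2, source = "B",
                                     target = "A", m = 1.5))),
    "migrant fraction"
  )
})

test_that("degrade_genotypes behaves at the rate extremes and in between", {
  co <- mk_cohort(matrix(0L, 10, 1000))
  expect_identical(degrade_genotypes(co, 0, 0), co)
  err <- degrade_genotypes(co, 0, 1, seed = 3)
  expect_false(any(err$geno == 0L, na.rm = TRUE))
  mis <- degrade_genotypes(co, 0.5, 0, seed = 4)
  frac <- mean(is.na(mis$geno))
  sd3 <- 3 * sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(frac - 0.5), sd3)
})

test_that("older splits yield stochastically less cross-population IBD", {
  med_cross <- vapply(c(5, 25, 100), function(g) {
    cfg <- breed_history(
      chrom_lengths = rep(5e7, 3), n_markers = 150, n_founder_haps = 50,
      populations = c(A = 10, B = 10), generations = g, seed = 400L + g
    )
    sim <- simulate_cohort(cfg)
    sums <- c(outer(1:10, 1:10, Vectorize(function(i, j) {
      s <- true_pair_ibd(sim$truth, sprintf("A_%02d", i), sprintf("B_%02d", j),
                         min_len = 1e6)
      sum(s$length)
    })))
    median(sums)
  }, numeric(1))
  expect_true(all(diff(med_cross) <= 0))
})

test_that("maximal IBD segment length matches the 100/(2g) cM expectation", {
  # Independent replicate histories, one cross-population pair each, with
  # population size scaled as 10g so within-population inbreeding (which
  # merges same-founder blocks and lengthens segments) stays negligible.
  setups <- list(list(g = 5, seeds = 30), list(g = 10, seeds = 20),
                 list(g = 25, seeds = 12))
  for (su in setups) {
    g <- su$g
    lens <- numeric(0)
    for (s in seq_len(su$seeds)) {
      cfg <- breed_history(
        chrom_lengths = rep(1e8, 5), n_markers = 10, n_founder_haps = 50,
        populations = c(A = 10L * g, B = 10L * g), generations = g,
        sample_sizes = c(A = 1, B = 1), seed = 500L + 101L * s + g
      )
      sim <- simulate_cohort(cfg)
      lens <- c(lens, true_pair_ibd(sim$truth, "A_01", "B_01")$length)
    }
    # 1 cM/Mb map: expected length 100/(2g) cM, with chromosome-end censoring
    expected_cM <- 1 / (2 * g / 100 + 1 / 100)
    got_cM <- mean(lens) / 1e6
    expect_gt(length(lens), 100)
    expect_lt(abs(got_cM - expected_cM) / expected_cM, 0.20,
              label = paste0("g=", g, " mean segment error"))
  }
})
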