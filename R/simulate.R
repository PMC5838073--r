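#' @title Synthetic breed-cohort simulator
#' @name synthetic_cohort
#' @description
#' Forward-in-time diploid Wright-Fisher simulation of closed populations
#' (breeds) with explicit founder-mosaic tracking. Every haplotype of every
#' individual is represented as a mosaic of founder-haplotype segments, so
#' true identity-by-descent, true autozygosity and true split generations are
#' available exactly, without inference. Crossovers are Poisson along the
#' genetic map (no interference); genotypes are emitted at array-density
#' markers whose founder allele frequencies follow a clipped symmetric Beta,
#' mimicking array ascertainment.
#'
#' Time is counted in generations before present: the sampled generation is
#' generation 0 and the founding generation is `generations`. A population
#' "created at generation g" exists at all times `t <= g`; its first members
#' are children of the source population's members at `t = g + 1`.
NULL

#' Describe a breed-formation history
#'
#' @param chrom_lengths numeric vector of chromosome lengths in bp (names
#'   optional; defaults `chr1`, `chr2`, ...).
#' @param n_markers total autosomal marker count, distributed across
#'   chromosomes proportionally to physical length.
#' @param cM_per_Mb recombination rate; default 1 cM/Mb (dog-genome-scale
#'   uniform map). May be a vector, one rate per chromosome.
#' @param n_founder_haps size of the ancestral founder-haplotype pool. This
#'   is the haploid size of the (implicit) panmictic ancestral population from
#'   which initial populations are drawn.
#' @param founder_beta shape parameters of the symmetric Beta distribution of
#'   founder allele frequencies (default `c(0.8, 0.8)`).
#' @param founder_clip frequency clipping range (default `c(0.05, 0.95)`),
#'   mimicking array ascertainment against rare variants.
#' @param populations named integer vector of initial population sizes,
#'   founded at generation `generations` from the founder pool.
#' @param generations founding depth in generations before present.
#' @param events list of population events, each a list with fields
#'   `type` (`"split"`, `"resize"` or `"admixture"`), `gen` (generations
#'   before present at which the event takes effect) and, depending on type:
#'   `source`/`target`/`size` for splits, `pop`/`size` for resizes
#'   (bottlenecks), `source`/`target`/`m` for admixture (each parent slot of
#'   the target generation is drawn from the source with probability `m`).
#' @param sample_sizes named integer vector of final diploid sample counts
#'   per population (defaults to the full final generation).
#' @param clades optional named character vector mapping population to clade
#'   label (defaults to one clade per population).
#' @param missing_rate genotype missingness rate applied to emitted calls.
#' @param selfing allow self-fertilisation (default `FALSE`).
#' @param seed random seed.
#' @return A `breed_history` configuration list.
#' @export
breed_history <- function(chrom_lengths = rep(1e8, 5),
                          n_markers = 10000,
                          cM_per_Mb = 1,
                          n_founder_haps = 100,
                          founder_beta = c(0.8, 0.8),
                          founder_clip = c(0.05, 0.95),
                          populations = c(pop1 = 25),
                          generations = 20,
                          events = list(),
                          sample_sizes = NULL,
                          clades = NULL,
                          missing_rate = 0,
                          selfing = FALSE,
                          seed = 1L) {
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  cM_per_Mb <- rep_len(cM_per_Mb, length(chrom_lengths))
  stopifnot(all(chrom_lengths > 0), n_markers >= 1, n_founder_haps >= 2,
            length(populations) >= 1, !is.null(names(populations)),
            all(populations >= 1), generations >= 0, missing_rate >= 0,
            missing_rate <= 1)
  gens <- vapply(events, function(e) e$gen, numeric(1))
  if (length(events)) {
    events <- events[order(-gens)]
    if (max(gens) >= generations) {
      stop("event at generation ", max(gens),
           " is not after the founding generation ", generations)
    }
  }
  for (e in events) {
    if (!e$type %in% c("split", "resize", "admixture")) {
      stop("unknown event type: ", e$type)
    }
    if (e$type == "admixture" && (e$m < 0 || e$m > 1)) {
      stop("migrant fraction m must lie in [0, 1]")
    }
    if (!is.null(e$size) && e$size < 1) stop("population sizes must be >= 1")
  }
  cfg <- list(
    chrom_lengths = chrom_lengths, n_markers = n_markers, cM_per_Mb = cM_per_Mb,
    n_founder_haps = as.integer(n_founder_haps), founder_beta = founder_beta,
    founder_clip = founder_clip, populations = populations,
    generations = generations, events = events, sample_sizes = sample_sizes,
    clades = clades, missing_rate = missing_rate, selfing = selfing,
    seed = as.integer(seed)
  )
  class(cfg) <- "breed_history"
  cfg
}

# --- mosaic primitives ------------------------------------------------------

# A haplotype on one chromosome is list(end = numeric, fnd = integer): the
# k-th segment covers (end[k-1], end[k]] with founder id fnd[k]; end[last]
# equals the chromosome length.

founder_hap <- function(chrom_lengths, fid) {
  lapply(chrom_lengths, function(len) list(end = len, fnd = fid))
}

# segments of `h` overlapping (lo, hi], with the last end clipped to hi
slice_mosaic <- function(h, lo, hi) {
  i1 <- findInterval(lo, h$end) + 1L          # first segment with end > lo
  i2 <- min(findInterval(hi, h$end, left.open = TRUE) + 1L, length(h$end))
  idx <- i1:i2
  e <- h$end[idx]
  e[length(e)] <- hi
  list(end = e, fnd = h$fnd[idx])
}

# crossover product of two single-chromosome haplotypes at given cut points
recombine_chrom <- function(h1, h2, cuts, len, first_a) {
  ncross <- length(cuts)
  bounds <- c(0, cuts, len)
  ends <- vector("list", ncross + 1L)
  fnds <- vector("list", ncross + 1L)
  for (i in seq_len(ncross + 1L)) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    if (hi <= lo) { ends[[i]] <- numeric(0); fnds[[i]] <- integer(0); next }
    src <- if (xor(i %% 2L == 1L, !first_a)) h1 else h2
    s <- slice_mosaic(src, lo, hi)
    ends[[i]] <- s$end; fnds[[i]] <- s$fnd
  }
  end <- unlist(ends, use.names = FALSE)
  fnd <- unlist(fnds, use.names = FALSE)
  if (length(fnd) > 1L) {
    keep <- c(fnd[-length(fnd)] != fnd[-1L], TRUE)
    end <- end[keep]; fnd <- fnd[keep]
  }
  list(end = end, fnd = fnd)
}

# one meiosis: crossovers Poisson along the genetic map, no interference
meiosis <- function(ind, chrom_lengths, cM_lens) {
  nh <- length(chrom_lengths)
  ncross <- stats::rpois(nh, cM_lens / 100)
  first_a <- stats::runif(nh) < 0.5
  out <- vector("list", nh)
  for (c in seq_len(nh)) {
    n <- ncross[c]
    if (n == 0L) {
      out[[c]] <- if (first_a[c]) ind[[1L]][[c]] else ind[[2L]][[c]]
      next
    }
    cuts <- stats::runif(n, 0, chrom_lengths[c])
    if (n > 1L) cuts <- sort.int(cuts, method = "quick")
    out[[c]] <- recombine_chrom(ind[[1L]][[c]], ind[[2L]][[c]], cuts,
                                chrom_lengths[c], first_a[c])
  }
  out
}

# --- population bookkeeping -------------------------------------------------

# population ancestry: for each population, when it was created and from what
pop_pedigree <- function(cfg) {
  created <- stats::setNames(rep(cfg$generations, length(cfg$populations)),
                             names(cfg$populations))
  parent <- stats::setNames(rep(NA_character_, length(cfg$populations)),
                            names(cfg$populations))
  for (e in cfg$events) {
    if (e$type == "split") {
      if (!e$source %in% names(created)) {
        stop("split of unknown source population: ", e$source)
      }
      if (created[e$source] <= e$gen) {
        stop("population ", e$source, " does not exist yet at generation ", e$gen)
      }
      created[e$target] <- e$gen
      parent[e$target] <- e$source
    } else if (!((e$pop %||% e$target) %in% names(created))) {
      stop("event references unknown population: ", e$pop %||% e$target)
    }
  }
  list(created = created, parent = parent)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# generation at which the lineages of two populations merge
split_generation <- function(ped, a, b) {
  pop_at <- function(p, t) {
    while (t > ped$created[[p]]) {
      if (is.na(ped$parent[[p]])) return("<founders>")
      p <- ped$parent[[p]]
    }
    p
  }
  if (a == b) return(0)
  # populations created at generation g were one population at g + 1
  for (t in 1:(max(ped$created) + 1)) {
    if (identical(pop_at(a, t), pop_at(b, t))) return(t - 1)
  }
  max(ped$created)
}

# --- the simulator ----------------------------------------------------------

#' Simulate a breed cohort with full ground truth
#'
#' Runs the configured history forward in time and emits an unphased
#' [new_cohort()], the matching truth-phase [new_phased_cohort()] and a
#' `truth_record` carrying founder mosaics, founder allele frequencies and
#' true split generations. The run is fully reproducible given `cfg$seed`.
#'
#' @param cfg a [breed_history()] configuration.
#' @return List with elements `cohort`, `phased` and `truth`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "breed_history"))
  set.seed(cfg$seed)
  chrom_lengths <- cfg$chrom_lengths
  cM_lens <- chrom_lengths / 1e6 * cfg$cM_per_Mb
  ped <- pop_pedigree(cfg)

  # founding generation
  G <- cfg$generations
  state <- lapply(cfg$populations, function(N) {
    lapply(seq_len(N), function(i) {
      fids <- sample.int(cfg$n_founder_haps, 2L, replace = TRUE)
      list(founder_hap(chrom_lengths, fids[1L]), founder_hap(chrom_lengths, fids[2L]))
    })
  })
  sizes <- cfg$populations

  events_at <- function(t) Filter(function(e) e$gen == t, cfg$events)

  if (G > 0) {
    for (t in seq(G - 1, 0)) {
      ev <- events_at(t)
      # splits first: they define which populations exist at t
      new_pops <- character(0)
      for (e in ev) {
        if (e$type == "split") {
          sizes[e$target] <- as.integer(e$size %||% sizes[[e$source]])
          new_pops <- c(new_pops, e$target)
        } else if (e$type == "resize") {
          sizes[e$pop] <- as.integer(e$size)
        }
      }
      adm <- list()
      for (e in ev) {
        if (e$type == "admixture") adm[[e$target]] <- e
      }
      alive <- names(sizes)
      nxt <- vector("list", length(alive))
      names(nxt) <- alive
      for (p in alive) {
        src_pop <- if (p %in% new_pops) state[[ped$parent[p]]] else state[[p]]
        if (is.null(src_pop)) stop("population ", p, " has no parents at generation ", t + 1)
        a <- adm[[p]]
        mig_pop <- if (!is.null(a)) state[[a$source]] else NULL
        if (!is.null(a) && is.null(mig_pop)) {
          stop("admixture source ", a$source, " does not exist at generation ", t + 1)
        }
        nxt[[p]] <- make_children(src_pop, sizes[[p]], mig_pop,
                                  if (is.null(a)) 0 else a$m,
                                  cfg$selfing, chrom_lengths, cM_lens)
      }
      state <- nxt
    }
  }

  # final sampling
  ss <- cfg$sample_sizes
  if (is.null(ss)) ss <- vapply(state, length, integer(1))
  ss <- ss[names(ss) %in% names(state)]
  samples <- list(); mosaics <- list()
  for (p in names(ss)) {
    k <- min(ss[[p]], length(state[[p]]))
    for (i in seq_len(k)) {
      sid <- sprintf("%s_%02d", p, i)
      samples[[sid]] <- p
      mosaics[[sid]] <- state[[p]][[i]]
    }
  }
  pops <- unlist(samples)
  clades <- cfg$clades
  if (is.null(clades)) clades <- stats::setNames(names(ss), names(ss))
  sample_tab <- data.frame(
    id = names(pops), breed = unname(pops),
    country = NA_character_, clade = unname(clades[pops]),
    stringsAsFactors = FALSE
  )

  # markers and founder alleles, then genotype emission
  n_per_chrom <- round(cfg$n_markers * chrom_lengths / sum(chrom_lengths))
  n_per_chrom[n_per_chrom < 1] <- 1L
  nsamp <- nrow(sample_tab)
  map_list <- vector("list", length(chrom_lengths))
  hap_list <- vector("list", length(chrom_lengths))
  freq_list <- vector("list", length(chrom_lengths))
  for (c in seq_along(chrom_lengths)) {
    Lc <- n_per_chrom[c]
    pos <- sort(sample.int(chrom_lengths[c], Lc))
    p <- stats::rbeta(Lc, cfg$founder_beta[1L], cfg$founder_beta[2L])
    p <- pmin(pmax(p, cfg$founder_clip[1L]), cfg$founder_clip[2L])
    falle <- matrix(stats::rbinom(cfg$n_founder_haps * Lc, 1L, rep(p, each = cfg$n_founder_haps)),
                    nrow = cfg$n_founder_haps)
    hap_c <- matrix(NA_integer_, 2L * nsamp, Lc)
    for (i in seq_len(nsamp)) {
      mos <- mosaics[[sample_tab$id[i]]]
      for (k in 1:2) {
        h <- mos[[k]][[c]]
        seg <- findInterval(pos, h$end, left.open = TRUE) + 1L
        seg[seg > length(h$fnd)] <- length(h$fnd)
        hap_c[2L * (i - 1L) + k, ] <- falle[cbind(h$fnd[seg], seq_len(Lc))]
      }
    }
    map_list[[c]] <- data.frame(
      chrom = names(chrom_lengths)[c],
      id = sprintf("%s_snp%05d", names(chrom_lengths)[c], seq_len(Lc)),
      cM = pos / 1e6 * cfg$cM_per_Mb[c], pos = pos,
      a1 = "A", a2 = "B", stringsAsFactors = FALSE
    )
    hap_list[[c]] <- hap_c
    freq_list[[c]] <- p
  }
  map <- do.call(rbind, map_list)
  hap <- do.call(cbind, hap_list)
  founder_freq <- unlist(freq_list, use.names = FALSE)

  phased <- new_phased_cohort(map, hap, sample_tab)
  geno <- hap[seq(1L, 2L * nsamp, by = 2L), , drop = FALSE] +
    hap[seq(2L, 2L * nsamp, by = 2L), , drop = FALSE]
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(length(geno)) < cfg$missing_rate, nrow(geno))
    geno[mask] <- NA_integer_
  }
  cohort <- new_cohort(map, geno, sample_tab)

  pops_u <- names(ss)
  sg <- matrix(0, length(pops_u), length(pops_u), dimnames = list(pops_u, pops_u))
  for (i in seq_along(pops_u)) {
    for (j in seq_along(pops_u)) {
      if (i < j) {
        sg[i, j] <- sg[j, i] <- split_generation(ped, pops_u[i], pops_u[j])
      }
    }
  }
  truth <- structure(
    list(mosaics = mosaics, chrom_lengths = chrom_lengths,
         founder_freq = founder_freq, split_gens = sg,
         samples = sample_tab, config = cfg),
    class = "truth_record"
  )
  list(cohort = cohort, phased = phased, truth = truth)
}

make_children <- function(parents, N, migrants, m, selfing, chrom_lengths, cM_lens) {
  np <- length(parents)
  children <- vector("list", N)
  for (i in seq_len(N)) {
    from_mig <- if (!is.null(migrants) && m > 0) stats::runif(2L) < m else c(FALSE, FALSE)
    if (!any(from_mig)) {
      idx <- if (np == 1L || selfing) {
        sample.int(np, 2L, replace = TRUE)
      } else {
        sample.int(np, 2L)
      }
      p1 <- parents[[idx[1L]]]; p2 <- parents[[idx[2L]]]
    } else if (all(from_mig)) {
      nm <- length(migrants)
      idx <- if (nm == 1L || selfing) sample.int(nm, 2L, replace = TRUE) else sample.int(nm, 2L)
      p1 <- migrants[[idx[1L]]]; p2 <- migrants[[idx[2L]]]
    } else {
      p1 <- parents[[sample.int(np, 1L)]]
      p2 <- migrants[[sample.int(length(migrants), 1L)]]
    }
    children[[i]] <- list(meiosis(p1, chrom_lengths, cM_lens),
                          meiosis(p2, chrom_lengths, cM_lens))
  }
  children
}

# --- truth queries ----------------------------------------------------------

# IBD segments between two single-chromosome mosaics
mosaic_ibd_chrom <- function(ha, hb) {
  ends <- sort(unique(c(ha$end, hb$end)))
  ia <- findInterval(ends, ha$end, left.open = TRUE) + 1L
  ib <- findInterval(ends, hb$end, left.open = TRUE) + 1L
  ia[ia > length(ha$fnd)] <- length(ha$fnd)
  ib[ib > length(hb$fnd)] <- length(hb$fnd)
  same <- ha$fnd[ia] == hb$fnd[ib]
  if (!any(same)) return(cbind(start = numeric(0), end = numeric(0)))
  r <- rle(same)
  hi_idx <- cumsum(r$lengths)
  lo_idx <- hi_idx - r$lengths + 1L
  keep <- r$values
  starts <- c(0, ends)[lo_idx[keep]] + 1
  stops <- ends[hi_idx[keep]]
  cbind(start = starts, end = stops)
}

#' True identity-by-descent segments for a sample pair
#'
#' Maximal same-founder intervals across the four haplotype pairings of two
#' individuals, read directly off the simulator's founder mosaics.
#'
#' @param truth a `truth_record` from [simulate_cohort()].
#' @param a,b sample ids.
#' @param min_len minimum segment length in bp (default 0).
#' @return data.frame with columns `chrom`, `start`, `end`, `pairing`
#'   (`"11"`, `"12"`, `"21"`, `"22"`), `length`.
#' @export
true_pair_ibd <- function(truth, a, b, min_len = 0) {
  stopifnot(inherits(truth, "truth_record"))
  for (s in c(a, b)) {
    if (!s %in% names(truth$mosaics)) stop("unknown sample id: ", s)
  }
  ma <- truth$mosaics[[a]]; mb <- truth$mosaics[[b]]
  chroms <- names(truth$chrom_lengths)
  out <- list()
  for (c in seq_along(chroms)) {
    for (i in 1:2) {
      for (j in 1:2) {
        seg <- mosaic_ibd_chrom(ma[[i]][[c]], mb[[j]][[c]])
        if (nrow(seg)) {
          out[[length(out) + 1L]] <- data.frame(
            chrom = chroms[c], start = seg[, 1L], end = seg[, 2L],
            pairing = paste0(i, j), stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      pairing = character(0), length = numeric(0)))
  }
  res <- do.call(rbind, out)
  res$length <- res$end - res$start + 1
  res[res$length >= min_len, , drop = FALSE]
}

#' True autozygosity of a sample
#'
#' Fraction of the genome where the two haplotype mosaics of a sample
#' reference the same founder haplotype.
#'
#' @param truth a `truth_record`.
#' @param id sample id.
#' @return Autozygous genome fraction in `[0, 1]`.
#' @export
true_autozygosity <- function(truth, id) {
  stopifnot(inherits(truth, "truth_record"))
  if (!id %in% names(truth$mosaics)) stop("unknown sample id: ", id)
  m <- truth$mosaics[[id]]
  tot <- 0
  for (c in seq_along(truth$chrom_lengths)) {
    seg <- mosaic_ibd_chrom(m[[1L]][[c]], m[[2L]][[c]])
    if (nrow(seg)) tot <- tot + sum(seg[, 2L] - seg[, 1L] + 1)
  }
  tot / sum(truth$chrom_lengths)
}

#' Inject missingness and genotyping error into a cohort
#'
#' Calls are masked and/or flipped independently at the stated rates; a
#' flipped call is replaced by one of the other two genotype classes chosen
#' uniformly.
#'
#' @param cohort a `cohort`.
#' @param missing_rate per-call masking probability.
#' @param error_rate per-call flip probability (applied to calls that survive
#'   masking).
#' @param seed random seed.
#' @return The degraded `cohort`.
#' @export
degrade_genotypes <- function(cohort, missing_rate = 0, error_rate = 0, seed = 1L) {
  validate_cohort(cohort)
  stopifnot(missing_rate >= 0, missing_rate <= 1, error_rate >= 0, error_rate <= 1)
  if (missing_rate == 0 && error_rate == 0) return(cohort)
  set.seed(seed)
  g <- cohort$geno
  if (error_rate > 0) {
    flip <- !is.na(g) & matrix(stats::runif(length(g)) < error_rate, nrow(g))
    nflip <- sum(flip)
    if (nflip) {
      g[flip] <- (g[flip] + sample(1:2, nflip, replace = TRUE)) %% 3L
    }
  }
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(length(g)) < missing_rate, nrow(g))
    g[mask] <- NA_integer_
  }
  new_cohort(cohort$map, g, cohort$samples)
}

#' @export
print.truth_record <- function(x, ...) {
  cat("<truth_record> ", length(x$mosaics), " samples, ",
      length(x$chrom_lengths), " chromosomes, founding depth ",
      x$config$generations, " generations\n", sep = "")
  invisible(x)
}
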