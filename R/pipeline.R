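#' @title End-to-end pipeline orchestration
#' @name pipeline_cli
#' @description
#' Runs the full analysis — simulate (or load), QC, breed subsampling,
#' bootstrap phylogeny, homozygosity metrics and status classification,
#' haplotype sharing with significance and dating — as one configured,
#' logged, reproducible unit. A single global seed is fanned out to
#' per-stage seeds by a fixed derivation, so identical configurations yield
#' byte-identical tabular outputs.
NULL

#' Pipeline configuration
#'
#' Exactly one of `simulation` or `plink_prefix` must be given.
#'
#' @param simulation a [breed_history()] config to simulate the input cohort.
#' @param plink_prefix path prefix of an input PLINK fileset.
#' @param plink_dialect `"binary"` or `"text"`.
#' @param phased_vcf optional phased VCF for the sharing stage (simulated
#'   runs use the simulator's truth phase).
#' @param qc a [qc_params()] set.
#' @param phylo a [phylo_params()] set (outgroup required).
#' @param roh a [roh_params()] set.
#' @param sharing a [sharing_params()] set.
#' @param timing a [timing_params()] set.
#' @param thresholds a [status_thresholds()] set.
#' @param mono_support monophyly-support level above which a breed counts as
#'   phylogenetically clustered (default 0.90, strict `>`).
#' @param out_dir output directory (created if needed).
#' @param seed global seed.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, plink_prefix = NULL,
                            plink_dialect = "binary", phased_vcf = NULL,
                            qc = qc_params(), phylo = phylo_params(),
                            roh = roh_params(), sharing = sharing_params(),
                            timing = timing_params(),
                            thresholds = status_thresholds(),
                            mono_support = 0.90,
                            out_dir = tempfile("breedscape_run_"),
                            seed = 1L) {
  if (is.null(simulation) == is.null(plink_prefix)) {
    stop("give exactly one of `simulation` or `plink_prefix`")
  }
  if (!is.null(plink_prefix)) {
    exts <- if (plink_dialect == "binary") c(".bed", ".bim", ".fam") else c(".ped", ".map")
    for (e in exts) {
      f <- paste0(plink_prefix, e)
      if (!file.exists(f)) stop("input file missing: ", f)
    }
  }
  if (!is.null(phased_vcf) && !file.exists(phased_vcf)) {
    stop("input file missing: ", phased_vcf)
  }
  if (is.null(phylo$outgroup)) stop("phylo$outgroup must be set")
  structure(list(simulation = simulation, plink_prefix = plink_prefix,
                 plink_dialect = plink_dialect, phased_vcf = phased_vcf,
                 qc = qc, phylo = phylo, roh = roh, sharing = sharing,
                 timing = timing, thresholds = thresholds,
                 mono_support = mono_support, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Stages run in fixed order: input, QC, subsampling, phylogeny, metrics,
#' sharing, report. A stage failure aborts with the stage name; outputs of
#' completed stages are preserved in `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the run `manifest`, output `paths` and the
#'   main in-memory `objects` (cohort, phylogeny, metrics, sharing tables).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  paths <- character(0)
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, secs = proc.time()[["elapsed"]] - t0)
  }
  stage <- function(name, expr) {
    r <- tryCatch(t_stage(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(seconds = round(r$secs, 3))
    r$value
  }

  # input ---------------------------------------------------------------
  phased <- NULL; truth <- NULL
  cohort <- stage("input", {
    if (!is.null(config$simulation)) {
      sim_cfg <- config$simulation
      sim_cfg$seed <- derive_seed(config$seed, "simulate")
      sim <- simulate_cohort(sim_cfg)
      phased <- sim$phased
      truth <- sim$truth
      sim$cohort
    } else {
      if (!is.null(config$phased_vcf)) {
        phased <- read_phased_vcf(config$phased_vcf)
      }
      read_plink(config$plink_prefix, config$plink_dialect)
    }
  })
  manifest$stages$input$n_samples <- nrow(cohort$samples)
  manifest$stages$input$n_markers <- nrow(cohort$map)

  # qc ------------------------------------------------------------------
  qc <- stage("qc", run_qc(cohort, config$qc))
  paths["qc_report"] <- file.path(config$out_dir, "qc_report.json")
  write_qc_report(qc$reports, paths["qc_report"])
  manifest$stages$qc$n_samples <- nrow(qc$cohort$samples)
  manifest$stages$qc$n_markers <- nrow(qc$cohort$map)

  # subsample -----------------------------------------------------------
  sub <- stage("subsample", subsample_breeds(
    qc$cohort, cap = config$phylo$cap,
    seed = derive_seed(config$seed, "subsample")
  ))
  manifest$stages$subsample$n_samples <- nrow(sub$samples)

  # phylogeny -----------------------------------------------------------
  ph <- stage("phylogeny", {
    pp <- config$phylo
    pp$seed <- derive_seed(config$seed, "phylo")
    bootstrap_consensus(sub, pp)
  })
  paths["tree"] <- file.path(config$out_dir, "consensus.nwk")
  write_tree(ph, paths["tree"])
  supports <- data.frame(
    breed = names(ph$support$breed_monophyly),
    monophyly_support = unname(ph$support$breed_monophyly),
    stringsAsFactors = FALSE
  )
  paths["supports"] <- write_tsv(supports,
                                 file.path(config$out_dir, "breed_support.tsv"))
  misclassified <- flag_misclassified(ph$support, config$phylo$threshold)
  manifest$stages$phylogeny$n_misclassified <- length(misclassified)

  # metrics -------------------------------------------------------------
  # the outgroup is a rooting device, not a study population
  keep <- setdiff(sub$samples$id[sub$samples$breed != config$phylo$outgroup],
                  misclassified)
  analysis_cohort <- subset_cohort(sub, samples = keep)
  metrics <- stage("metrics", {
    mono <- ph$support$breed_monophyly > config$mono_support
    breed_metrics(analysis_cohort, monophyly = mono, params = config$roh,
                  thresholds = config$thresholds,
                  seed = derive_seed(config$seed, "metrics"))
  })
  paths["metrics"] <- write_tsv(metrics,
                                file.path(config$out_dir, "breed_metrics.tsv"))

  # sharing -------------------------------------------------------------
  sharing_tab <- NULL
  if (!is.null(phased)) {
    sharing_tab <- stage("sharing", {
      ids <- analysis_cohort$samples$id
      ph_sub <- subset_phased(phased, ids)
      sums_cross <- all_pair_sharing(ph_sub, params = config$sharing)
      within_pairs <- within_breed_pairs(ph_sub$samples)
      sums_within <- if (nrow(within_pairs)) {
        all_pair_sharing(ph_sub, within_pairs, params = config$sharing)
      } else {
        data.frame(a = character(0), b = character(0), bp = numeric(0))
      }
      stats <- breed_pair_medians(sums_cross, ph_sub$samples)
      if (nrow(stats)) {
        thr <- significance_threshold(stats, config$sharing$percentile)
        stats <- flag_significant(stats, thr)
        wmed <- within_breed_medians(sums_within, ph_sub$samples)
        dt <- lapply(seq_len(nrow(stats)), function(k) {
          divergence_time(stats$median_bp[k],
                          wmed[stats$breed_a[k]], wmed[stats$breed_b[k]],
                          config$timing)
        })
        stats$generations <- vapply(dt, `[[`, numeric(1), "generations")
        stats$years <- vapply(dt, `[[`, numeric(1), "years")
        stats$calendar_year <- vapply(dt, `[[`, numeric(1), "calendar_year")
        stats$same_population <- vapply(dt, function(d) {
          if (is.na(d$same_population)) NA else d$same_population
        }, logical(1))
        stats$threshold_bp <- thr
      }
      stats
    })
    paths["sharing"] <- write_tsv(sharing_tab,
                                  file.path(config$out_dir, "breed_pair_stats.tsv"))
    paths["network"] <- file.path(config$out_dir, "sharing_network.tsv")
    sharing_network_export(sharing_tab, paths["network"])
  }

  # report --------------------------------------------------------------
  manifest$outputs <- lapply(as.list(paths), function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)))
  })
  paths["manifest"] <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, paths = paths,
                 objects = list(cohort = qc$cohort, subsampled = sub,
                                phylogeny = ph, misclassified = misclassified,
                                metrics = metrics, sharing = sharing_tab,
                                truth = truth)))
}

# subset a phased cohort to the given sample ids
subset_phased <- function(phased, ids) {
  si <- match(ids, phased$samples$id)
  si <- si[!is.na(si)]
  rows <- as.vector(rbind(2L * si - 1L, 2L * si))
  new_phased_cohort(phased$map, phased$hap[rows, , drop = FALSE],
                    phased$samples[si, , drop = FALSE])
}

within_breed_pairs <- function(samples) {
  rows <- list()
  for (b in unique(samples$breed)) {
    ids <- samples$id[samples$breed == b]
    if (length(ids) >= 2L) {
      idx <- utils::combn(length(ids), 2L)
      rows[[b]] <- data.frame(a = ids[idx[1L, ]], b = ids[idx[2L, ]],
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(a = character(0), b = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

within_breed_medians <- function(sums, samples) {
  breed_of <- stats::setNames(samples$breed, samples$id)
  out <- stats::setNames(rep(NA_real_, length(unique(samples$breed))),
                         unique(samples$breed))
  for (b in names(out)) {
    v <- sums$bp[breed_of[sums$a] == b & breed_of[sums$b] == b]
    if (length(v)) out[b] <- stats::median(v)
  }
  out
}

#' Write input files for external admixture tools
#'
#' Emits the allele-count table consumed by graph-based admixture inference
#' (gzipped, one column per population, `a1,a2` counts per SNP) and a plain
#' two-rows-per-individual STRUCTURE-format genotype matrix. Sites
#' monomorphic in the cohort are excluded from the allele-count table and
#' counted in the return value.
#'
#' @param cohort a QC'd `cohort`.
#' @param dir output directory.
#' @return Invisibly, list with `treemix` and `structure` paths and
#'   `n_monomorphic` excluded sites.
#' @export
emit_external_tool_inputs <- function(cohort, dir) {
  validate_cohort(cohort)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pops <- unique(cohort$samples$breed)
  g <- cohort$geno
  p_alt <- colMeans(g, na.rm = TRUE) / 2
  mono <- is.nan(p_alt) | p_alt == 0 | p_alt == 1
  keep <- which(!mono)

  tm_path <- file.path(dir, "treemix_input.frq.gz")
  con <- gzfile(tm_path, "w")
  writeLines(paste(gsub("[ \t]+", "_", pops), collapse = " "), con)
  cnt <- matrix("", length(keep), length(pops))
  for (pi in seq_along(pops)) {
    rows <- which(cohort$samples$breed == pops[pi])
    gp <- g[rows, keep, drop = FALSE]
    n1 <- colSums(2L - gp, na.rm = TRUE)   # allele-1 count
    n2 <- colSums(gp, na.rm = TRUE)        # allele-2 count
    cnt[, pi] <- paste0(n1, ",", n2)
  }
  writeLines(apply(cnt, 1L, paste, collapse = " "), con)
  close(con)

  st_path <- file.path(dir, "structure_input.str")
  conn <- file(st_path, "w")
  pop_idx <- match(cohort$samples$breed, pops)
  for (i in seq_len(nrow(cohort$samples))) {
    gi <- g[i, ]
    al1 <- ifelse(is.na(gi), -9L, ifelse(gi >= 1L, ifelse(gi == 2L, 2L, 1L), 1L))
    al2 <- ifelse(is.na(gi), -9L, ifelse(gi >= 1L, 2L, 1L))
    id <- cohort$samples$id[i]
    writeLines(paste(c(id, pop_idx[i], al1), collapse = " "), conn)
    writeLines(paste(c(id, pop_idx[i], al2), collapse = " "), conn)
  }
  close(conn)
  invisible(list(treemix = tm_path, structure = st_path,
                 n_monomorphic = sum(mono)))
}

#' Parse a treemix allele-count file back into counts
#'
#' Round-trip reader for [emit_external_tool_inputs()] output, mainly for
#' validation.
#'
#' @param path the `.frq.gz` file.
#' @return List with `pops` and an integer array `counts`
#'   (sites x pops x 2 alleles).
#' @export
read_treemix_counts <- function(path) {
  lines <- readLines(gzfile(path))
  pops <- strsplit(lines[1L], " ", fixed = TRUE)[[1L]]
  body <- lines[-1L]
  counts <- array(0L, c(length(body), length(pops), 2L))
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], " ", fixed = TRUE)[[1L]]
    ab <- vapply(strsplit(parts, ",", fixed = TRUE), as.integer, integer(2))
    counts[i, , ] <- t(ab)
  }
  list(pops = pops, counts = counts)
}
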