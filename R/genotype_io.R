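#' @title PLINK and phased-VCF input/output
#' @name genotype_io
#' @description
#' Readers and writers for the two PLINK dialects (text `.ped`/`.map` and
#' binary `.bed`/`.bim`/`.fam`, SNP-major) and for phased VCF v4.2. All
#' writers are deterministic given a cohort. The PLINK family id (FID) column
#' carries the population (breed) label.
#'
#' The text dialect does not record allele orientation, so [read_plink()]
#' assigns `a1`/`a2` lexicographically for text input; the binary dialect
#' preserves orientation through the `.bim` file. Heterozygotes are written
#' with alleles in sorted order so that write-read-write round trips are
#' byte-identical.
NULL

#' Read a PLINK fileset into a cohort
#'
#' @param prefix path prefix (without extension).
#' @param dialect `"text"` (`.ped`/`.map`) or `"binary"` (`.bed`/`.bim`/`.fam`).
#' @return A [new_cohort()] object. Missing calls are `NA`; the allele coding
#'   is recorded in the marker map (`a1`, `a2`).
#' @export
read_plink <- function(prefix, dialect = c("binary", "text")) {
  dialect <- match.arg(dialect)
  if (dialect == "text") read_plink_text(prefix) else read_plink_binary(prefix)
}

read_plink_text <- function(prefix) {
  map_file <- paste0(prefix, ".map")
  ped_file <- paste0(prefix, ".ped")
  if (!file.exists(map_file)) stop("no such file: ", map_file)
  if (!file.exists(ped_file)) stop("no such file: ", ped_file)

  map_raw <- utils::read.table(map_file, header = FALSE, stringsAsFactors = FALSE,
                               col.names = c("chrom", "id", "cM", "pos"),
                               colClasses = c("character", "character", "numeric", "numeric"))
  L <- nrow(map_raw)

  lines <- readLines(ped_file)
  n <- length(lines)
  if (n == 0L) stop("empty ped file: ", ped_file)
  geno <- matrix(NA_integer_, n, L)
  a1 <- rep(NA_character_, L)
  a2 <- rep(NA_character_, L)
  ids <- breeds <- character(n)

  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * L) {
      stop("malformed line in ", ped_file, " at line ", i, ": expected ",
           6L + 2L * L, " fields, got ", length(f))
    }
    breeds[i] <- f[1L]
    ids[i] <- f[2L]
    al1 <- f[seq(7L, by = 2L, length.out = L)]
    al2 <- f[seq(8L, by = 2L, length.out = L)]
    miss <- al1 == "0" | al2 == "0"
    # discover allele symbols per marker (lexicographic orientation)
    for (j in which(!miss)) {
      for (al in c(al1[j], al2[j])) {
        if (is.na(a1[j])) {
          a1[j] <- al
        } else if (a1[j] != al && is.na(a2[j])) {
          a2[j] <- al
        } else if (al != a1[j] && al != a2[j]) {
          stop("more than two alleles at marker ", map_raw$id[j], " in ", ped_file,
               " at line ", i)
        }
      }
    }
    known <- !miss
    geno[i, known] <- (al1[known] != a1[known]) + (al2[known] != a1[known])
  }
  if (anyDuplicated(ids)) stop("duplicate sample id in ", ped_file)

  # orient lexicographically: a1 < a2 when both present
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
    geno[, swap] <- 2L - geno[, swap]
  }
  a1[is.na(a1)] <- "0"
  a2[is.na(a2)] <- "0"

  map <- data.frame(chrom = map_raw$chrom, id = map_raw$id, cM = map_raw$cM,
                    pos = map_raw$pos, a1 = a1, a2 = a2,
                    stringsAsFactors = FALSE)
  new_cohort(map, geno, data.frame(id = ids, breed = breeds, stringsAsFactors = FALSE))
}

read_plink_binary <- function(prefix) {
  bed_file <- paste0(prefix, ".bed")
  bim_file <- paste0(prefix, ".bim")
  fam_file <- paste0(prefix, ".fam")
  for (f in c(bed_file, bim_file, fam_file)) {
    if (!file.exists(f)) stop("no such file: ", f)
  }
  bim <- utils::read.table(bim_file, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cM", "pos", "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "numeric", "character", "character"))
  fam <- utils::read.table(fam_file, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  if (anyDuplicated(fam$iid)) stop("duplicate sample id in ", fam_file)
  n <- nrow(fam); L <- nrow(bim)

  raw <- readBin(bed_file, what = "raw", n = file.size(bed_file))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b)) {
    stop("not a PLINK bed file: ", bed_file)
  }
  if (raw[3L] != as.raw(0x01)) stop("only SNP-major bed files are supported: ", bed_file)
  body <- raw[-(1:3)]
  bpm <- ceiling(n / 4)                      # bytes per marker
  if (length(body) != bpm * L) {
    stop("bed payload size mismatch in ", bed_file, ": expected ", bpm * L,
         " bytes, found ", length(body))
  }
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8L * bpm)  # bit rows x L
  b0 <- bits[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  b1 <- bits[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  v <- b0 + 2L * b1
  geno <- matrix(NA_integer_, n, L)
  geno[v == 0L] <- 0L
  geno[v == 2L] <- 1L
  geno[v == 3L] <- 2L
  # v == 1 stays NA (missing)
  map <- bim
  new_cohort(map, geno,
             data.frame(id = fam$iid, breed = fam$fid, stringsAsFactors = FALSE))
}

#' Write a cohort as a PLINK fileset
#'
#' @param cohort a `cohort`.
#' @param prefix output path prefix.
#' @param dialect `"text"` or `"binary"`.
#' @return The paths written, invisibly.
#' @export
write_plink <- function(cohort, prefix, dialect = c("binary", "text")) {
  dialect <- match.arg(dialect)
  validate_cohort(cohort)
  if (dialect == "text") write_plink_text(cohort, prefix) else write_plink_binary(cohort, prefix)
}

fid_label <- function(x) gsub("[ \t]+", "_", x)

write_plink_text <- function(cohort, prefix) {
  map_file <- paste0(prefix, ".map")
  ped_file <- paste0(prefix, ".ped")
  m <- cohort$map
  utils::write.table(
    data.frame(m$chrom, m$id, m$cM, m$pos),
    map_file, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE
  )
  n <- nrow(cohort$samples); L <- nrow(m)
  lo <- pmin(m$a1, m$a2)   # canonical het order
  hi <- pmax(m$a1, m$a2)
  con <- file(ped_file, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    g <- cohort$geno[i, ]
    al1 <- ifelse(is.na(g), "0", ifelse(g == 0L, m$a1, ifelse(g == 2L, m$a2, lo)))
    al2 <- ifelse(is.na(g), "0", ifelse(g == 0L, m$a1, ifelse(g == 2L, m$a2, hi)))
    fields <- character(2L * L)
    fields[seq(1L, by = 2L, length.out = L)] <- al1
    fields[seq(2L, by = 2L, length.out = L)] <- al2
    writeLines(paste(c(fid_label(cohort$samples$breed[i]), cohort$samples$id[i],
                       "0", "0", "0", "-9", fields), collapse = " "), con)
  }
  invisible(c(ped_file, map_file))
}

write_plink_binary <- function(cohort, prefix) {
  bed_file <- paste0(prefix, ".bed")
  bim_file <- paste0(prefix, ".bim")
  fam_file <- paste0(prefix, ".fam")
  m <- cohort$map
  utils::write.table(
    data.frame(m$chrom, m$id, m$cM, m$pos, m$a1, m$a2),
    bim_file, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE
  )
  s <- cohort$samples
  utils::write.table(
    data.frame(fid_label(s$breed), s$id, 0, 0, 0, -9),
    fam_file, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE
  )
  n <- nrow(s); L <- nrow(m)
  npad <- 4L * ceiling(n / 4)
  # two-bit codes, low bit first: 00 hom a1, 01 missing, 10 het, 11 hom a2
  g <- cohort$geno
  b0 <- matrix(0L, npad, max(L, 1L))
  b1 <- matrix(0L, npad, max(L, 1L))
  if (L > 0L && n > 0L) {
    for (i in seq_len(n)) {
      gi <- g[i, ]
      b0[i, ] <- ifelse(is.na(gi), 1L, ifelse(gi == 2L, 1L, 0L))
      b1[i, ] <- ifelse(is.na(gi), 0L, ifelse(gi >= 1L, 1L, 0L))
    }
  }
  bits <- matrix(0L, 2L * npad, max(L, 1L))
  bits[seq(1L, 2L * npad, by = 2L), ] <- b0
  bits[seq(2L, 2L * npad, by = 2L), ] <- b1
  payload <- if (L > 0L) packBits(as.integer(bits), type = "raw") else raw(0)
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), payload), bed_file)
  invisible(c(bed_file, bim_file, fam_file))
}

#' Read a phased VCF into a phased cohort
#'
#' Biallelic sites with phased (`|`-separated) GT fields are kept.
#' Multiallelic records are skipped with a reported count.
#'
#' @param path VCF file (plain or bgzipped).
#' @param samples optional data.frame with columns `id`, `breed` (and
#'   optionally `country`, `clade`) used to label the VCF samples. Samples
#'   absent from the table get breed `"unspecified"`.
#' @param strict if `TRUE` (default) an unphased (`/`-separated) genotype is
#'   an error; if `FALSE` such records are dropped.
#' @return A [new_phased_cohort()] object.
#' @export
read_phased_vcf <- function(path, samples = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no records in ", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    message("read_phased_vcf: skipping ", sum(multi), " multiallelic record(s)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L) stop("no genotyped samples in ", path)
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  unphased <- !is.na(gt) & grepl("/", gt, fixed = TRUE)
  if (any(unphased)) {
    if (strict) {
      i <- which(rowSums(unphased) > 0L)[1L]
      stop("unphased genotype at ", fix$CHROM[i], ":", fix$POS[i],
           " (strict mode); rerun with strict = FALSE to drop such records")
    }
    drop <- rowSums(unphased) > 0L
    message("read_phased_vcf: dropping ", sum(drop), " unphased record(s)")
    gt <- gt[!drop, , drop = FALSE]
    fix <- fix[!drop, , drop = FALSE]
  }
  if (nrow(fix) == 0L) stop("no phased biallelic records left in ", path)

  ids <- colnames(gt)
  n <- length(ids); L <- nrow(fix)
  hap <- matrix(NA_integer_, 2L * n, L)
  parse_allele <- function(x) {
    out <- suppressWarnings(as.integer(x))
    out[x == "."] <- NA_integer_
    out
  }
  for (s in seq_len(n)) {
    parts <- strsplit(gt[, s], "|", fixed = TRUE)
    h1 <- parse_allele(vapply(parts, function(p) if (length(p) >= 1L) p[1L] else ".", ""))
    h2 <- parse_allele(vapply(parts, function(p) if (length(p) >= 2L) p[2L] else ".", ""))
    h1[is.na(gt[, s])] <- NA_integer_
    h2[is.na(gt[, s])] <- NA_integer_
    hap[2L * s - 1L, ] <- h1
    hap[2L * s, ] <- h2
  }
  map <- data.frame(
    chrom = fix$CHROM,
    id = ifelse(is.na(fix$ID) | fix$ID == ".", paste0(fix$CHROM, ":", fix$POS), fix$ID),
    cM = 0,
    pos = as.numeric(fix$POS),
    a1 = fix$REF,
    a2 = fix$ALT,
    stringsAsFactors = FALSE
  )
  stab <- data.frame(id = ids, breed = "unspecified", stringsAsFactors = FALSE)
  if (!is.null(samples)) {
    hit <- match(stab$id, samples$id)
    ok <- !is.na(hit)
    stab$breed[ok] <- samples$breed[hit[ok]]
    if (!is.null(samples$country)) stab$country <- samples$country[hit]
    if (!is.null(samples$clade)) stab$clade <- samples$clade[hit]
  }
  new_phased_cohort(map, hap, stab)
}

#' Write a phased cohort as VCF v4.2
#'
#' @param phased a `phased_cohort`.
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(phased, path) {
  stopifnot(inherits(phased, "phased_cohort"))
  m <- phased$map
  n <- nrow(phased$samples)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=breedscape", con)
  for (ch in unique(m$chrom)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch,
                       as.integer(max(m$pos[m$chrom == ch])) + 1L), con)
  }
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", phased$samples$id), collapse = "\t"), con)
  al <- function(x) ifelse(is.na(x), ".", as.character(x))
  h1 <- phased$hap[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  h2 <- phased$hap[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  for (j in seq_len(nrow(m))) {
    gts <- paste0(al(h1[, j]), "|", al(h2[, j]))
    writeLines(paste(c(m$chrom[j], format(m$pos[j], scientific = FALSE), m$id[j],
                       m$a1[j], m$a2[j], ".", "PASS", ".", "GT", gts),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Merge two cohorts on their shared markers
#'
#' Markers are matched by (chromosome, position). Allele orientation in `b`
#' is harmonized to `a` by allele-symbol matching; a marker whose allele sets
#' are incompatible (e.g. a strand-ambiguous mismatch) is dropped and counted.
#' Samples are concatenated; sample ids must be disjoint.
#'
#' @param a,b cohorts.
#' @return The merged `cohort` on the marker intersection, with a
#'   `merge_report` attribute (`n_shared`, `n_recoded`, `n_dropped`).
#' @export
merge_cohorts <- function(a, b) {
  validate_cohort(a); validate_cohort(b)
  if (any(b$samples$id %in% a$samples$id)) {
    stop("sample ids overlap between cohorts; merge needs disjoint ids")
  }
  key_a <- paste(a$map$chrom, a$map$pos)
  key_b <- paste(b$map$chrom, b$map$pos)
  ia <- which(key_a %in% key_b)
  if (length(ia) == 0L) stop("cohorts share no markers")
  ib <- match(key_a[ia], key_b)

  same <- a$map$a1[ia] == b$map$a1[ib] & a$map$a2[ia] == b$map$a2[ib]
  swapped <- a$map$a1[ia] == b$map$a2[ib] & a$map$a2[ia] == b$map$a1[ib] & !same
  bad <- !(same | swapped)

  keep <- !bad
  ia <- ia[keep]; ib <- ib[keep]
  swapped <- swapped[keep]
  if (length(ia) == 0L) stop("no allele-compatible shared markers")

  gb <- b$geno[, ib, drop = FALSE]
  if (any(swapped)) gb[, swapped] <- 2L - gb[, swapped]
  geno <- rbind(a$geno[, ia, drop = FALSE], gb)
  out <- new_cohort(a$map[ia, , drop = FALSE], geno,
                    rbind(a$samples, b$samples))
  attr(out, "merge_report") <- list(
    n_shared = length(ia) + sum(bad),
    n_recoded = sum(swapped),
    n_dropped = sum(bad)
  )
  out
}
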