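#' Read a phased VCF into a cohort
#'
#' Reads a VCF (optionally bgzipped) with phased `GT` fields (`a|b`) for all
#' samples. Multiallelic and non-SNP records are skipped with a message; an
#' unphased (`a/b`) or missing genotype is a hard error naming the offending
#' record and sample, since the downstream similarity metric is undefined
#' across gaps. After loading, allele codes are recoded so 1 is the minor
#' allele and per-SNP minor allele frequencies are stored
#' (see [compute_allele_frequencies()]).
#'
#' @param path path to a VCF file.
#' @param region optional chromosome label to restrict to.
#' @param map optional genetic map (see [read_genetic_map()]) used to fill
#'   interpolated cM positions.
#' @return A [phased_cohort()] with `maf` filled in.
#' @export
read_phased_vcf <- function(path, region = NULL, map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (!is.null(region)) {
    sel <- fix$CHROM == region
    fix <- fix[sel, , drop = FALSE]
    gt <- gt[sel, , drop = FALSE]
  }
  biallelic_snp <- !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & fix$ALT != "."
  if (any(!biallelic_snp))
    message("read_phased_vcf: skipped ", sum(!biallelic_snp),
            " non-biallelic/non-SNP record(s)")
  fix <- fix[biallelic_snp, , drop = FALSE]
  gt <- gt[biallelic_snp, , drop = FALSE]
  if (nrow(fix) == 0L) stop("no biallelic SNP records found")

  ok <- grepl("^[01]\\|[01]$", gt)
  if (!all(ok)) {
    idx <- which(!ok)[1L]
    bad_r <- (idx - 1L) %% nrow(gt) + 1L
    bad_c <- (idx - 1L) %/% nrow(gt) + 1L
    stop("unphased or missing genotype '", gt[bad_r, bad_c],
         "' at ", fix$CHROM[bad_r], ":", fix$POS[bad_r],
         " for sample ", colnames(gt)[bad_c])
  }
  samples <- colnames(gt)
  n <- length(samples)
  a1 <- substr(gt, 1L, 1L) == "1"
  a2 <- substr(gt, 3L, 3L) == "1"

  variants <- data.frame(
    chrom = fix$CHROM,
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    stringsAsFactors = FALSE
  )
  ord <- order(match(variants$chrom, unique(variants$chrom)), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  a1 <- a1[ord, , drop = FALSE]; a2 <- a2[ord, , drop = FALSE]

  haps <- list()
  for (ch in unique(variants$chrom)) {
    sel <- variants$chrom == ch
    h <- matrix(0L, nrow = 2L * n, ncol = sum(sel))
    h[seq(1L, 2L * n, by = 2L), ] <- t(a1[sel, , drop = FALSE]) + 0L
    h[seq(2L, 2L * n, by = 2L), ] <- t(a2[sel, , drop = FALSE]) + 0L
    haps[[ch]] <- h
  }
  cohort <- phased_cohort(samples, variants, haps)
  cohort <- compute_allele_frequencies(cohort)
  if (!is.null(map)) cohort <- attach_genetic_map(cohort, map)
  cohort
}

#' Write a cohort as a phased VCF
#'
#' Emits a minimal phased VCF (one `GT` field per sample, `|`-separated)
#' with the stored allele codes: haplotype slot A is written first, so after
#' [apply_orientation()] slot A carries parental set 1 on every chromosome.
#'
#' @param cohort a [phased_cohort()].
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(cohort, path) {
  n <- n_samples(cohort)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=crossphase",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t")
  ), con)
  for (ch in cohort$chromosomes) {
    sel <- which(cohort$variants$chrom == ch)
    v <- cohort$variants[sel, , drop = FALSE]
    h <- cohort$haplotypes[[ch]]
    gtA <- h[seq(1L, 2L * n, by = 2L), , drop = FALSE]
    gtB <- h[seq(2L, 2L * n, by = 2L), , drop = FALSE]
    gt_txt <- matrix(paste0(gtA, "|", gtB), nrow = n)     # n x m
    lines <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                   sep = "\t")
    body <- apply(gt_txt, 2L, paste, collapse = "\t")
    writeLines(paste(lines, body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a genetic (recombination) map
#'
#' Reads a whitespace/tab-delimited text file with one header line and at
#' least three columns: chromosome, physical position (bp), and cumulative
#' genetic position (cM). Only the first three columns are used.
#'
#' @param path path to the map file (may be gzipped).
#' @return A `genetic_map`: data.frame with columns `chrom`, `pos`, `cM`,
#'   cM non-decreasing in bp within each chromosome.
#' @export
read_genetic_map <- function(path) {
  d <- read.table(path, header = TRUE, stringsAsFactors = FALSE)[, 1:3]
  names(d) <- c("chrom", "pos", "cM")
  genetic_map(d)
}

#' Construct/validate a genetic map object
#'
#' @param d data.frame with columns `chrom`, `pos` (bp), `cM`.
#' @return The validated data.frame with class `genetic_map`.
#' @export
genetic_map <- function(d) {
  stopifnot(all(c("chrom", "pos", "cM") %in% names(d)))
  d$chrom <- as.character(d$chrom)
  d <- d[order(match(d$chrom, unique(d$chrom)), d$pos), , drop = FALSE]
  for (ch in unique(d$chrom)) {
    s <- d[d$chrom == ch, ]
    if (nrow(s) < 2L) stop("genetic map needs >= 2 anchors on chromosome ", ch)
    if (is.unsorted(s$pos, strictly = TRUE))
      stop("map bp positions must be strictly increasing on chromosome ", ch)
    if (is.unsorted(s$cM)) stop("map cM must be non-decreasing on chromosome ", ch)
  }
  rownames(d) <- NULL
  class(d) <- c("genetic_map", "data.frame")
  d
}

#' Interpolate genetic position
#'
#' Linear interpolation of cumulative cM between map anchor points; positions
#' outside the anchored range take the boundary cM value.
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome label.
#' @param pos_bp physical positions (bp) to interpolate at.
#' @return numeric vector of cM positions.
#' @export
interpolate_genetic_position <- function(map, chrom, pos_bp) {
  s <- map[map$chrom == chrom, ]
  if (nrow(s) < 2L) stop("no map anchors for chromosome ", chrom)
  approx(s$pos, s$cM, xout = pos_bp, rule = 2)$y
}

#' Fill interpolated cM positions into a cohort's variant table
#'
#' @param cohort a [phased_cohort()].
#' @param map a [genetic_map()] covering the cohort's chromosomes.
#' @return The cohort with `variants$cM` filled.
#' @export
attach_genetic_map <- function(cohort, map) {
  for (ch in cohort$chromosomes) {
    sel <- cohort$variants$chrom == ch
    cohort$variants$cM[sel] <-
      interpolate_genetic_position(map, ch, cohort$variants$pos[sel])
  }
  cohort
}
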