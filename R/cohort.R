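#' Construct a phased cohort
#'
#' A `phased_cohort` holds, for each chromosome, the two haplotypes of every
#' individual as rows of a 0/1 allele matrix, together with per-variant
#' metadata. Allele code 1 conventionally denotes the minor allele (enforced
#' by [compute_allele_frequencies()] with `recode = TRUE`); the two haplotype
#' slots (A = first, B = second) of an individual carry arbitrary
#' per-chromosome labels that acquire cross-chromosome meaning only after
#' phasing.
#'
#' @param samples character vector of unique sample identifiers (length n).
#' @param variants data.frame with columns `chrom`, `id`, `pos` (1-based bp),
#'   `ref`, `alt`, and optionally `cM` and `maf`; rows ordered by chromosome
#'   and strictly increasing position within chromosome.
#' @param haplotypes named list (one element per chromosome, in the order
#'   chromosomes first appear in `variants`) of integer 0/1 matrices with
#'   `2 * n` rows; rows `2i - 1` and `2i` are the A and B haplotypes of
#'   sample `i`, columns are that chromosome's variants in order.
#' @return An object of class `phased_cohort`.
#' @export
phased_cohort <- function(samples, variants, haplotypes) {
  stopifnot(is.character(samples), !anyDuplicated(samples))
  n <- length(samples)
  variants$chrom <- as.character(variants$chrom)
  chroms <- unique(variants$chrom)
  if (!identical(sort(names(haplotypes)), sort(chroms)))
    stop("haplotype list names must match the chromosomes in `variants`")
  haplotypes <- haplotypes[chroms]
  for (ch in chroms) {
    h <- haplotypes[[ch]]
    m <- sum(variants$chrom == ch)
    if (nrow(h) != 2L * n || ncol(h) != m)
      stop("haplotype matrix for chromosome ", ch, " must be ", 2L * n, " x ", m)
    if (anyNA(h) || !all(h == 0L | h == 1L))
      stop("haplotype codes must be 0/1 with no missing values (chromosome ", ch, ")")
    pos <- variants$pos[variants$chrom == ch]
    if (is.unsorted(pos, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
    storage.mode(haplotypes[[ch]]) <- "integer"
  }
  if (is.null(variants$cM)) variants$cM <- NA_real_
  if (is.null(variants$maf)) variants$maf <- NA_real_
  rownames(variants) <- NULL
  structure(
    list(samples = samples, chromosomes = chroms,
         variants = variants, haplotypes = haplotypes),
    class = "phased_cohort"
  )
}

#' @export
print.phased_cohort <- function(x, ...) {
  cat("phased_cohort:", length(x$samples), "samples,",
      nrow(x$variants), "SNPs on", length(x$chromosomes), "chromosome(s)\n")
  invisible(x)
}

#' Number of samples / variants in a cohort
#' @param cohort a [phased_cohort()].
#' @return integer count.
#' @export
n_samples <- function(cohort) length(cohort$samples)

#' @rdname n_samples
#' @export
n_variants <- function(cohort) nrow(cohort$variants)

# Row indices of a sample's two haplotype slots.
hap_rows <- function(cohort, sample_id) {
  i <- match(sample_id, cohort$samples)
  if (is.na(i)) stop("unknown sample: ", sample_id)
  c(2L * i - 1L, 2L * i)
}

#' Diploid genotype dosages
#'
#' Sums the two haplotype slots to give the 0/1/2 dosage of allele code 1
#' for every sample at every variant of a chromosome.
#'
#' @param cohort a [phased_cohort()].
#' @param chrom chromosome label; `NULL` (default) concatenates all
#'   chromosomes in variant order.
#' @return integer matrix, samples x variants.
#' @export
diploid_genotypes <- function(cohort, chrom = NULL) {
  chroms <- if (is.null(chrom)) cohort$chromosomes else chrom
  n <- n_samples(cohort)
  mats <- lapply(chroms, function(ch) {
    h <- cohort$haplotypes[[ch]]
    h[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
      h[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  })
  g <- do.call(cbind, mats)
  rownames(g) <- cohort$samples
  g
}

#' Compute per-SNP minor allele frequencies
#'
#' Computes the frequency of allele code 1 over all `2n` haplotypes of each
#' SNP and stores `maf = min(freq, 1 - freq)` in the variant table. With
#' `recode = TRUE` (default) columns whose code-1 frequency exceeds 0.5 are
#' flipped (and REF/ALT swapped) so code 1 is always the minor allele — the
#' orientation assumed by [pihat()] and [psi_window()]. Monomorphic SNPs
#' (maf 0) are flagged in a logical `monomorphic` column; they must be
#' removed by [qc_filter()] before similarity computation.
#'
#' @param cohort a [phased_cohort()].
#' @param recode flip allele codes so 1 is the minor allele.
#' @return The cohort with `maf` (and possibly flipped codes) filled in.
#' @export
compute_allele_frequencies <- function(cohort, recode = TRUE) {
  maf <- numeric(n_variants(cohort))
  flipped <- logical(n_variants(cohort))
  for (ch in cohort$chromosomes) {
    sel <- which(cohort$variants$chrom == ch)
    freq1 <- colMeans(cohort$haplotypes[[ch]])
    if (recode) {
      fl <- freq1 > 0.5
      if (any(fl)) {
        cohort$haplotypes[[ch]][, fl] <- 1L - cohort$haplotypes[[ch]][, fl]
        freq1[fl] <- 1 - freq1[fl]
        flipped[sel] <- fl
      }
    }
    maf[sel] <- pmin(freq1, 1 - freq1)
  }
  if (any(flipped)) {
    r <- cohort$variants$ref[flipped]
    cohort$variants$ref[flipped] <- cohort$variants$alt[flipped]
    cohort$variants$alt[flipped] <- r
  }
  cohort$variants$maf <- maf
  cohort$variants$monomorphic <- maf == 0
  cohort
}

#' Variant quality-control filter
#'
#' Retains biallelic SNPs with minor allele frequency `>= maf_min` and a
#' 1-df Hardy-Weinberg equilibrium chi-square goodness-of-fit p-value
#' `> hwe_p_min` (expected genotype counts from the estimated allele
#' frequency). Monomorphic SNPs always fail. Defaults are the standard
#' cohort-QC settings (MAF >= 5%, HWE p > .0005).
#'
#' @param cohort a [phased_cohort()]; allele frequencies are (re)computed.
#' @param maf_min minimum minor allele frequency.
#' @param hwe_p_min HWE chi-square p-value threshold (exclusive).
#' @param keep_ids optional character vector: restrict to these variant ids
#'   before the statistical filters (a user-supplied include-list).
#' @return The filtered, re-indexed cohort. Errors if any chromosome loses
#'   all of its SNPs.
#' @export
qc_filter <- function(cohort, maf_min = 0.05, hwe_p_min = 0.0005,
                      keep_ids = NULL) {
  cohort <- compute_allele_frequencies(cohort)
  keep <- rep(TRUE, n_variants(cohort))
  if (!is.null(keep_ids)) keep <- keep & cohort$variants$id %in% keep_ids
  keep <- keep & cohort$variants$maf >= maf_min
  hwe_p <- hwe_pvalues(cohort)
  keep <- keep & !is.na(hwe_p) & hwe_p > hwe_p_min
  subset_variants(cohort, keep)
}

#' Hardy-Weinberg equilibrium chi-square p-values
#'
#' 1-df goodness-of-fit test of observed genotype counts against
#' Hardy-Weinberg expectations computed from the estimated allele frequency.
#'
#' @param cohort a [phased_cohort()].
#' @return numeric vector of p-values, one per variant (NA for monomorphic
#'   SNPs, where the test is undefined).
#' @export
hwe_pvalues <- function(cohort) {
  n <- n_samples(cohort)
  out <- numeric(0)
  for (ch in cohort$chromosomes) {
    g <- diploid_genotypes(cohort, ch)
    n2 <- colSums(g == 2L); n1 <- colSums(g == 1L); n0 <- n - n2 - n1
    p <- (2 * n2 + n1) / (2 * n)                  # frequency of allele 1
    e0 <- n * (1 - p)^2; e1 <- n * 2 * p * (1 - p); e2 <- n * p^2
    chi2 <- (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2
    pv <- pchisq(chi2, df = 1, lower.tail = FALSE)
    pv[p == 0 | p == 1] <- NA_real_
    out <- c(out, pv)
  }
  out
}

# Keep a logical subset of variants, re-indexing per-chromosome matrices.
subset_variants <- function(cohort, keep) {
  stopifnot(length(keep) == n_variants(cohort))
  for (ch in cohort$chromosomes) {
    sel <- cohort$variants$chrom == ch
    if (!any(keep[sel]))
      stop("qc_filter removed every SNP on chromosome ", ch)
    cohort$haplotypes[[ch]] <-
      cohort$haplotypes[[ch]][, keep[sel], drop = FALSE]
  }
  cohort$variants <- cohort$variants[keep, , drop = FALSE]
  rownames(cohort$variants) <- NULL
  cohort
}

# Column indices (within chromosome) and global row indices for a chromosome.
chrom_index <- function(cohort, chrom) which(cohort$variants$chrom == chrom)
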