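#' Diploid SNP relatedness (pi-hat)
#'
#' The standard genetic-relationship-matrix estimator of relatedness between
#' two diploid genotype vectors:
#' `(1/m) * sum_k (x_fk - 2 p_k)(x_ik - 2 p_k) / (2 p_k (1 - p_k))`,
#' where `p_k` is the minor allele frequency of SNP `k`. Expected values are
#' ~0.5 for parent-offspring or full siblings, ~0.25 for 2nd-degree
#' relatives, ~0 for unrelateds.
#'
#' @param x_f,x_i diploid genotype dosage vectors (0/1/2) of equal length.
#' @param maf per-SNP minor allele frequencies in (0, 0.5].
#' @return numeric scalar.
#' @export
pihat <- function(x_f, x_i, maf) {
  m <- length(x_f)
  if (length(x_i) != m || length(maf) != m) stop("pihat: length mismatch")
  if (any(maf <= 0) || any(maf >= 1)) stop("pihat: maf must lie in (0, 1)")
  mean((x_f - 2 * maf) * (x_i - 2 * maf) / (2 * maf * (1 - maf)))
}

#' Relatedness of one focal individual to every other cohort member
#'
#' @param cohort a [phased_cohort()] with allele frequencies computed.
#' @param focal focal sample id.
#' @param genotypes optional precomputed [diploid_genotypes()] matrix for
#'   the whole cohort, or a [pihat_prep()] object (reused across focal
#'   individuals).
#' @return named numeric vector of pi-hat values for all non-focal samples.
#' @export
pihat_all <- function(cohort, focal, genotypes = NULL) {
  prep <- if (inherits(genotypes, "pihat_prep")) genotypes
          else pihat_prep(cohort, genotypes)
  f <- match(focal, cohort$samples)
  if (is.na(f)) stop("unknown focal sample: ", focal)
  v <- as.vector(prep$d %*% (prep$d[f, ] * prep$w)) / prep$m
  setNames(v, cohort$samples)[-f]
}

#' Precompute the centered genotype matrix for relatedness
#'
#' Centers the diploid dosage matrix at `2 * maf` once so that repeated
#' [pihat_all()] calls across focal individuals are a single matrix-vector
#' product each.
#'
#' @inheritParams pihat_all
#' @return A `pihat_prep` object.
#' @export
pihat_prep <- function(cohort, genotypes = NULL) {
  if (is.null(genotypes)) genotypes <- diploid_genotypes(cohort)
  maf <- cohort$variants$maf
  if (anyNA(maf)) stop("allele frequencies not computed; run qc_filter()")
  if (any(maf <= 0)) stop("monomorphic SNPs present; run qc_filter()")
  structure(list(d = sweep(genotypes, 2L, 2 * maf),
                 w = 1 / (2 * maf * (1 - maf)), m = ncol(genotypes)),
            class = "pihat_prep")
}

#' Exclude close relatives of a focal individual
#'
#' Returns the non-focal individuals whose genome-wide relatedness
#' ([pihat()]) with the focal individual is below `threshold` (default 0.33,
#' which removes parents, offspring, and full siblings — the uninformative
#' or leakage-prone partners — while retaining 2nd-degree and more distant
#' relatives).
#'
#' @inheritParams pihat_all
#' @param threshold exclusion threshold on pi-hat.
#' @return character vector of retained partner ids, with the excluded ids
#'   in attribute `"excluded"`. Errors if no partner remains.
#' @export
exclude_close_relatives <- function(cohort, focal, threshold = 0.33,
                                    genotypes = NULL) {
  p <- pihat_all(cohort, focal, genotypes)
  partners <- names(p)[p < threshold]
  if (length(partners) == 0L)
    stop("no partners with pihat < ", threshold, " for focal ", focal,
         "; phasing impossible")
  structure(partners, excluded = names(p)[p >= threshold])
}

# Dampened per-site term values for an identical-allele match at each site:
# ((a - p)^2 / (p (1 - p)))^exponent for allele a in {0, 1}.
psi_weights <- function(maf, exponent) {
  if (any(maf <= 0 | maf >= 1)) stop("psi: maf must lie in (0, 1)")
  list(w0 = (maf / (1 - maf))^exponent,
       w1 = ((1 - maf) / maf)^exponent)
}

#' Haploid windowed similarity (psi-hat)
#'
#' The similarity between one focal haplotype and one partner haplotype
#' within a window: both are restricted to the sites where the focal
#' individual is heterozygous (the phase-informative sites), the longest
#' contiguous run of identical alleles is located, and the run is scored as
#' the sum over its sites of `((x_k - p_k)^2 / (p_k (1 - p_k)))^exponent`.
#' The 1/5 exponent dampens the otherwise disproportionate weight of
#' rare-allele matches. A run of identical alleles always has non-negative
#' terms, so psi-hat >= 0; it is 0 when no restricted site matches. Ties in
#' run length are broken by the larger score, then by leftmost start.
#'
#' @param focal_hap,other_hap 0/1 allele vectors over one window's SNPs.
#' @param het_mask logical vector: focal-heterozygous sites.
#' @param maf per-SNP minor allele frequencies.
#' @param exponent dampening exponent applied to each term.
#' @return numeric scalar >= 0.
#' @export
psi_window <- function(focal_hap, other_hap, het_mask, maf, exponent = 1 / 5) {
  stopifnot(length(other_hap) == length(focal_hap),
            length(het_mask) == length(focal_hap),
            length(maf) == length(focal_hap))
  keep <- which(het_mask)
  if (length(keep) == 0L) return(0)
  w <- psi_weights(maf[keep], exponent)
  .psi_window_cpp(as.integer(focal_hap[keep]), as.integer(other_hap[keep]),
                  w$w0, w$w1)
}

#' Best-haplotype windowed similarity (psi-hat-star)
#'
#' For a named focal haplotype slot and a partner, the larger of the two
#' [psi_window()] values against the partner's two haplotypes, raised to
#' `power`. Taking the within-window maximum makes the score robust to the
#' partner's own within-chromosome phase errors (each window may match
#' either partner haplotype); the power amplifies the contrast between
#' background similarity and shared-ancestry signal.
#'
#' @param cohort a [phased_cohort()] with allele frequencies computed.
#' @param focal,partner sample ids.
#' @param window one row of a `window_set` (with `snp_start`/`snp_end`).
#' @param hap `"A"` or `"B"`: which focal haplotype slot.
#' @param power amplification exponent applied after the max.
#' @param exponent per-site dampening exponent (see [psi_window()]).
#' @return numeric scalar >= 0.
#' @export
psi_star <- function(cohort, focal, partner, window, hap = c("A", "B"),
                     power = 2, exponent = 1 / 5) {
  hap <- match.arg(hap)
  ch <- window$chrom
  offset <- min(which(cohort$variants$chrom == ch)) - 1L
  cols <- (window$snp_start:window$snp_end) - offset
  h <- cohort$haplotypes[[ch]]
  fr <- hap_rows(cohort, focal); pr <- hap_rows(cohort, partner)
  f <- h[if (hap == "A") fr[1L] else fr[2L], cols]
  het <- h[fr[1L], cols] != h[fr[2L], cols]
  maf <- cohort$variants$maf[window$snp_start:window$snp_end]
  max(psi_window(f, h[pr[1L], cols], het, maf, exponent),
      psi_window(f, h[pr[2L], cols], het, maf, exponent))^power
}

#' Build the psi-star tensor for a focal individual
#'
#' Computes, for both focal haplotype slots and every window, the
#' [psi_star()] value against every retained partner, giving the two
#' window-by-partner profile matrices whose cross-window correlations drive
#' phasing. Windows containing no focal-heterozygous SNP yield all-zero
#' vectors and are flagged unusable.
#'
#' @param cohort a [phased_cohort()] with allele frequencies computed.
#' @param focal focal sample id.
#' @param windows a `window_set` with SNPs assigned ([assign_snps()]).
#' @param partners character vector of partner ids; `NULL` (default) runs
#'   [exclude_close_relatives()] with `pihat_max`.
#' @param pihat_max relatedness exclusion threshold (used when `partners`
#'   is `NULL`).
#' @param power,exponent see [psi_star()].
#' @param genotypes optional precomputed [diploid_genotypes()] matrix
#'   (only used for the relatedness exclusion).
#' @return A `psi_star_tensor`: list with `focal`, `partners`, `excluded`,
#'   `windows`, matrices `A` and `B` (windows x partners), and logical
#'   `usable` per window.
#' @export
build_psi_star_tensor <- function(cohort, focal, windows, partners = NULL,
                                  pihat_max = 0.33, power = 2,
                                  exponent = 1 / 5, genotypes = NULL) {
  if (is.null(partners))
    partners <- exclude_close_relatives(cohort, focal, pihat_max, genotypes)
  excluded <- attr(partners, "excluded")
  if (is.null(excluded))
    excluded <- setdiff(cohort$samples, c(focal, partners))
  partners <- as.vector(partners, "character")
  W <- nrow(windows); P <- length(partners)
  A <- matrix(0, W, P, dimnames = list(NULL, partners))
  B <- matrix(0, W, P, dimnames = list(NULL, partners))
  usable <- logical(W)
  fr <- hap_rows(cohort, focal)
  pidx <- match(partners, cohort$samples)
  pA0 <- 2L * pidx - 2L; pB0 <- 2L * pidx - 1L   # 0-based rows for C++
  for (ch in unique(windows$chrom)) {
    offset <- min(which(cohort$variants$chrom == ch)) - 1L
    h <- cohort$haplotypes[[ch]]
    het_all <- h[fr[1L], ] != h[fr[2L], ]
    for (w in which(windows$chrom == ch)) {
      cols <- (windows$snp_start[w]:windows$snp_end[w]) - offset
      het <- which(het_all[cols])
      if (length(het) == 0L) next
      hcols <- cols[het]
      wts <- psi_weights(cohort$variants$maf[hcols + offset], exponent)
      m <- .psi_star_window_cpp(t(h[, hcols, drop = FALSE]),
                                fr[1L] - 1L, fr[2L] - 1L,
                                pA0, pB0, wts$w0, wts$w1, power)
      A[w, ] <- m[1L, ]; B[w, ] <- m[2L, ]
      usable[w] <- TRUE
    }
  }
  if (any(!usable))
    message("build_psi_star_tensor: ", sum(!usable),
            " window(s) with no focal-het SNP for ", focal)
  structure(list(focal = focal, partners = as.vector(partners, "character"),
                 excluded = excluded, windows = windows,
                 A = A, B = B, usable = usable),
            class = "psi_star_tensor")
}

#' @export
print.psi_star_tensor <- function(x, ...) {
  cat("psi_star_tensor: focal", x$focal, "-", nrow(x$A), "windows x",
      ncol(x$A), "partners;", sum(x$usable), "usable window(s)\n")
  invisible(x)
}
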