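#' Trio-based parental-origin ground truth
#'
#' At every site where the focal offspring is heterozygous, parental diploid
#' genotypes determine which parent transmitted each allele whenever at
#' least one parent is homozygous; sites where all three individuals are
#' heterozygous are `unresolved`, and impossible configurations (e.g. both
#' parents homozygous for the same allele) are `mendelian_error`.
#'
#' @param cohort a [phased_cohort()] containing the focal offspring.
#' @param focal offspring sample id.
#' @param parent1,parent2 diploid genotype dosage vectors (0/1/2 copies of
#'   allele code 1) over the cohort's variants, in variant order.
#' @param fill_unresolved if `TRUE`, triple-heterozygous sites are filled
#'   from the nearest resolved site on the same chromosome, assuming the
#'   offspring's within-chromosome phase is consistent between the two
#'   (filled sites get status `"filled"` and enter the ACPA denominator).
#'   The default excludes them, which keeps the truth independent of
#'   within-chromosome phase quality.
#' @return A `trio_truth`: list with `focal` and `calls`, a data.frame over
#'   focal-heterozygous sites with the global variant `row`, `chrom`,
#'   `status` (`resolved` / `unresolved` / `mendelian_error`) and `origin1`
#'   (1 or 2: the parent that transmitted allele 1; NA when not resolved).
#'   Warns if the Mendelian-error rate exceeds 1% (likely sample mismatch).
#' @export
trio_ground_truth <- function(cohort, focal, parent1, parent2,
                              fill_unresolved = FALSE) {
  m <- n_variants(cohort)
  stopifnot(length(parent1) == m, length(parent2) == m)
  fr <- hap_rows(cohort, focal)
  hapA <- unlist(lapply(cohort$chromosomes, function(ch)
    cohort$haplotypes[[ch]][fr[1L], ]), use.names = FALSE)
  g <- hapA + unlist(lapply(cohort$chromosomes, function(ch)
    cohort$haplotypes[[ch]][fr[2L], ]), use.names = FALSE)
  het <- which(g == 1L)
  g1 <- parent1[het]; g2 <- parent2[het]
  origin1 <- rep(NA_integer_, length(het))
  status <- rep("unresolved", length(het))
  err <- (g1 == 0L & g2 == 0L) | (g1 == 2L & g2 == 2L)
  res1 <- !err & ((g1 == 2L) | (g1 == 1L & g2 == 0L))  # parent 1 gave allele 1
  res2 <- !err & ((g1 == 0L & g2 > 0L) | (g1 == 1L & g2 == 2L))
  origin1[res1] <- 1L; origin1[res2] <- 2L
  status[res1 | res2] <- "resolved"
  status[err] <- "mendelian_error"
  if (mean(err) > 0.01)
    warning("trio_ground_truth: Mendelian-error rate ",
            round(100 * mean(err), 2), "% > 1%; check sample identities")
  calls <- data.frame(row = het, chrom = cohort$variants$chrom[het],
                      status = status, origin1 = origin1,
                      stringsAsFactors = FALSE)
  if (fill_unresolved && any(status == "unresolved") && any(res1 | res2)) {
    for (ch in unique(calls$chrom)) {
      in_ch <- which(calls$chrom == ch)
      res_ch <- in_ch[calls$status[in_ch] == "resolved"]
      if (length(res_ch) == 0L) next
      for (k in in_ch[calls$status[in_ch] == "unresolved"]) {
        j <- res_ch[which.min(abs(calls$row[res_ch] - calls$row[k]))]
        # parent carried by slot A at the nearest resolved site; assume no
        # switch between the two sites
        parent_A <- if (hapA[calls$row[j]] == 1L) calls$origin1[j]
                    else 3L - calls$origin1[j]
        calls$origin1[k] <- if (hapA[calls$row[k]] == 1L) parent_A
                            else 3L - parent_A
        calls$status[k] <- "filled"
      }
    }
  }
  structure(list(focal = focal, calls = calls), class = "trio_truth")
}

#' Across-chromosome phasing accuracy (ACPA)
#'
#' Scores an across-chromosome phased focal individual against trio truth:
#' at every resolved site, checks whether the allele carried by haplotype
#' slot A ("parental set 1") was truly transmitted by the same parent. The
#' global mapping of set 1 to a parent is chosen once, genome-wide, to
#' maximise the proportion correct (so the genome-wide score is always
#' >= 50%, with 50% the random-assignment expectation); per-chromosome
#' scores use that same global mapping and may fall below 50%.
#'
#' @param cohort a [phased_cohort()] whose focal individual has been
#'   oriented (e.g. by [apply_orientation()]).
#' @param truth a `trio_truth` for the same focal and variant set.
#' @return An `acpa_report`: list with `acpa_percent`, `per_chromosome`
#'   (data.frame `chrom`, `acpa_percent`, `n_scored`), `n_scored_snps`,
#'   `orientation_used` (`TRUE` if set 1 was mapped to parent 2), and
#'   `focal`.
#' @export
acpa <- function(cohort, truth) {
  calls <- truth$calls[truth$calls$status %in% c("resolved", "filled"), ,
                       drop = FALSE]
  if (nrow(calls) == 0L) stop("acpa: no resolved sites in truth")
  fr <- hap_rows(cohort, truth$focal)
  allele_A <- integer(nrow(calls))
  for (ch in unique(calls$chrom)) {
    offset <- min(which(cohort$variants$chrom == ch)) - 1L
    sel <- calls$chrom == ch
    allele_A[sel] <- cohort$haplotypes[[ch]][fr[1L], calls$row[sel] - offset]
  }
  # parent that transmitted the slot-A allele at each site
  parent_A <- ifelse(allele_A == 1L, calls$origin1, 3L - calls$origin1)
  agree <- parent_A == 1L
  flip <- mean(agree) < 0.5
  if (flip) agree <- !agree
  per_chrom <- do.call(rbind, lapply(unique(calls$chrom), function(ch) {
    sel <- calls$chrom == ch
    data.frame(chrom = ch, acpa_percent = 100 * mean(agree[sel]),
               n_scored = sum(sel), stringsAsFactors = FALSE)
  }))
  structure(list(acpa_percent = 100 * mean(agree), per_chromosome = per_chrom,
                 n_scored_snps = nrow(calls), orientation_used = flip,
                 focal = truth$focal),
            class = "acpa_report")
}

#' @export
print.acpa_report <- function(x, ...) {
  cat("ACPA for", x$focal, ":", round(x$acpa_percent, 2), "% over",
      x$n_scored_snps, "resolved SNPs\n")
  invisible(x)
}

#' Summarise ACPA by closest-relative relatedness
#'
#' Groups focal individuals by the highest [pihat()] relatedness to any
#' non-focal cohort member, binned at the midpoints between the canonical
#' degree expectations (0.5, 0.25, 0.125, 0.0625), and reports per-stratum
#' mean and median ACPA and the share of individuals phased perfectly.
#'
#' @param reports list of `acpa_report` objects (one per focal individual).
#' @param cohort the analysis [phased_cohort()] (used for relatedness).
#' @param genotypes optional precomputed [diploid_genotypes()] matrix.
#' @return data.frame with one row per occupied stratum: `stratum`, `n`,
#'   `mean_acpa`, `median_acpa`, `fraction_perfect`; empty for an empty
#'   report list.
#' @export
stratify_by_relatedness <- function(reports, cohort, genotypes = NULL) {
  empty <- data.frame(stratum = character(), n = integer(),
                      mean_acpa = numeric(), median_acpa = numeric(),
                      fraction_perfect = numeric(), stringsAsFactors = FALSE)
  if (length(reports) == 0L) return(empty)
  if (!inherits(genotypes, "pihat_prep")) genotypes <- pihat_prep(cohort, genotypes)
  focals <- vapply(reports, function(r) r$focal, character(1))
  scores <- vapply(reports, function(r) r$acpa_percent, numeric(1))
  closest <- vapply(focals, function(f)
    max(pihat_all(cohort, f, genotypes)), numeric(1))
  breaks <- c(-Inf, 0.03125, 0.09375, 0.1875, 0.375, Inf)
  labels <- c("unrelated", "4th degree", "3rd degree", "2nd degree",
              "1st degree")
  stratum <- cut(closest, breaks, labels, right = FALSE)
  out <- do.call(rbind, lapply(levels(stratum), function(s) {
    sel <- stratum == s
    if (!any(sel)) return(NULL)
    data.frame(stratum = s, n = sum(sel), mean_acpa = mean(scores[sel]),
               median_acpa = median(scores[sel]),
               fraction_perfect = mean(scores[sel] == 100),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) empty else out
}
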