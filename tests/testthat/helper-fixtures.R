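# Small fixture builders shared across test files.

# Phased cohort from explicit haplotype matrices: `haps` is a named list per
# chromosome of 2n x m 0/1 matrices (rows 2i-1/2i = sample i slots A/B).
cohort_from_matrices <- function(haps, maf = NULL, samples = NULL,
                                 positions = NULL) {
  n <- nrow(haps[[1]]) / 2
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(n))
  variants <- do.call(rbind, lapply(names(haps), function(ch) {
    m <- ncol(haps[[ch]])
    pos <- if (is.null(positions)) seq_len(m) else positions[[ch]]
    data.frame(chrom = ch, id = paste0(ch, ":", pos), pos = pos,
               ref = "A", alt = "C", stringsAsFactors = FALSE)
  }))
  cohort <- phased_cohort(samples, variants, haps)
  if (!is.null(maf)) cohort$variants$maf <- rep_len(maf, nrow(variants))
  cohort
}

# Single-chromosome cohort covering one window spanning all SNPs.
whole_chrom_window <- function(cohort, chrom = cohort$chromosomes[1]) {
  rows <- which(cohort$variants$chrom == chrom)
  ws <- data.frame(chrom = chrom, start_bp = 0,
                   end_bp = max(cohort$variants$pos[rows]) + 1,
                   start_cM = 0, end_cM = 1, span_cM = 1, window = 1L,
                   snp_start = min(rows), snp_end = max(rows),
                   n_snps = length(rows), stringsAsFactors = FALSE)
  class(ws) <- c("window_set", "data.frame")
  ws
}

# Linear genetic map: 1 cM per Mb, anchors every `step_bp`.
linear_map <- function(chroms = "chr1", len_cM = 100, step_bp = 1e6) {
  genetic_map(do.call(rbind, lapply(chroms, function(ch) {
    pos <- seq(0, len_cM * 1e6, by = step_bp)
    data.frame(chrom = ch, pos = pos, cM = pos / 1e6)
  })))
}

# Write a minimal phased VCF fixture; `gt` is a variants x samples character
# matrix of GT strings.
write_vcf_fixture <- function(path, chrom, pos, ref, alt, gt,
                              samples = paste0("S", seq_len(ncol(gt)))) {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(pos), function(k)
    paste(c(chrom[k], pos[k], ".", ref[k], alt[k], ".", "PASS", ".", "GT",
            gt[k, ]), collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  path
}
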