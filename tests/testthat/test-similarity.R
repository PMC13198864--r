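test_that("pihat matches single-SNP hand arithmetic and rejects bad maf", {
  expect_equal(pihat(2, 2, 0.5), 2)
  expect_equal(pihat(2, 0, 0.5), -2)
  expect_error(pihat(c(1, 1), c(1, 1), c(0.5, 0)), "maf")
  expect_error(pihat(c(1, 1), 1, 0.5), "length")
})

test_that("relatedness exclusion removes parents and keeps unrelateds", {
  set.seed(41)
  cfg <- sim_config(n_focal = 1, n_unrelated = 30, include_parents = TRUE,
                    n_chromosomes = 2, snps_per_chrom = 2500)
  sim <- qc_filter_sim(simulate_cohort(cfg))
  f <- sim$focal_ids[1]
  p <- pihat_all(sim$cohort, f)
  expect_gt(p[paste0(f, ".p1")], 0.4)  # parent-offspring relatedness ~ 0.5
  expect_lt(max(abs(p[grep("^U", names(p))])), 0.2)  # unrelateds ~ 0
  partners <- exclude_close_relatives(sim$cohort, f)
  expect_false(any(paste0(f, c(".p1", ".p2")) %in% partners))
  expect_setequal(attr(partners, "excluded"), paste0(f, c(".p1", ".p2")))
  # no-op bound retains everyone
  expect_length(exclude_close_relatives(sim$cohort, f, threshold = 1.1),
                n_samples(sim$cohort) - 1)
})

test_that("psi_window scores the longest identical run over focal-het sites", {
  het <- rep(TRUE, 3); p <- rep(0.5, 3)
  # identical minor alleles at p = 0.5 contribute unit terms
  expect_equal(psi_window(c(1, 1, 1), c(1, 1, 1), het, p), 3)
  # mismatch at every het site -> empty run
  expect_equal(psi_window(c(1, 0, 1), c(0, 1, 0), het, p), 0)
  # longest run wins, not the total of all matches
  x <- c(1, 1, 0, 1, 1, 1); y <- c(1, 1, 1, 1, 1, 1)
  expect_equal(psi_window(x, y, rep(TRUE, 6), rep(0.5, 6)), 3)
  # non-het sites are excluded before runs are formed
  expect_equal(psi_window(c(1, 0, 1), c(1, 1, 1), c(TRUE, FALSE, TRUE),
                          rep(0.5, 3)), 2)
})

test_that("rare-allele matches weigh more, but the damping caps the excess", {
  t_rare <- psi_window(1, 1, TRUE, 0.05)
  t_common <- psi_window(1, 1, TRUE, 0.5)
  expect_gt(t_rare, t_common)
  expect_lt(t_rare, 5 * t_common)
})

test_that("psi_window agrees with the brute-force all-runs oracle", {
  set.seed(42)
  for (case in 1:300) {
    L <- sample(1:50, 1)
    maf <- runif(L, 0.05, 0.5)
    x <- rbinom(L, 1, 0.5)
    y <- rbinom(L, 1, 0.5)
    het <- runif(L) < 0.7
    expect_equal(psi_window(x, y, het, maf), psi_oracle(x, y, het, maf),
                 tolerance = 1e-10)
  }
})

test_that("psi_star takes the better partner haplotype, then the power", {
  # focal het at all 3 sites; partner hap A matches focal A everywhere,
  # partner hap B matches nowhere
  haps <- list(chr1 = rbind(c(1L, 1L, 1L), c(0L, 0L, 0L),
                            c(1L, 1L, 1L), c(0L, 0L, 0L)))
  cohort <- cohort_from_matrices(haps, maf = 0.5)
  ws <- whole_chrom_window(cohort)
  expect_equal(psi_star(cohort, "S01", "S02", ws[1, ], hap = "A"), 9)
  # swapping the partner's slot labels changes nothing
  haps2 <- haps
  haps2$chr1[3:4, ] <- haps2$chr1[4:3, ]
  cohort2 <- cohort_from_matrices(haps2, maf = 0.5)
  expect_equal(psi_star(cohort2, "S01", "S02", ws[1, ], hap = "A"), 9)
  expect_equal(psi_star(cohort, "S01", "S02", ws[1, ], hap = "B"), 9)
})

test_that("the psi-star tensor has the right shape, sign, and partner axis", {
  set.seed(43)
  cfg <- sim_config(n_focal = 1, n_unrelated = 12, n_chromosomes = 2,
                    snps_per_chrom = 400, chrom_length_cM = 60)
  sim <- qc_filter_sim(simulate_cohort(cfg))
  ws <- make_windows(sim$map, sim$cohort)
  f <- sim$focal_ids[1]
  tensor <- build_psi_star_tensor(sim$cohort, f, ws)
  expect_s3_class(tensor, "psi_star_tensor")
  expect_equal(dim(tensor$A), c(nrow(ws), n_samples(sim$cohort) - 1))
  expect_identical(colnames(tensor$A), tensor$partners)
  expect_true(all(tensor$A >= 0) && all(tensor$B >= 0))
  # explicit partner order permutes the partner axis identically everywhere
  perm <- rev(tensor$partners)
  t2 <- build_psi_star_tensor(sim$cohort, f, ws, partners = perm)
  expect_equal(t2$A, tensor$A[, perm])
  expect_equal(t2$B, tensor$B[, perm])
})

test_that("a planted shared segment lifts that partner far above the rest", {
  set.seed(44)
  n <- 30; m <- 300
  hap <- matrix(rbinom(2 * n * m, 1, 0.3), 2 * n, m)
  # partner S02's haplotype B copies focal S01's haplotype A over a segment
  hap[4, 101:250] <- hap[1, 101:250]
  cohort <- compute_allele_frequencies(
    cohort_from_matrices(list(chr1 = hap)), recode = FALSE)
  ws <- whole_chrom_window(cohort)
  tensor <- build_psi_star_tensor(cohort, "S01", ws,
                                  partners = cohort$samples[-1])
  s2 <- tensor$A[1, "S02"]
  expect_gt(s2, 10 * median(tensor$A[1, ]))
  # flipping the partner's slot labels within the window changes no value
  hap2 <- hap; hap2[3:4, ] <- hap2[4:3, ]
  cohort2 <- compute_allele_frequencies(
    cohort_from_matrices(list(chr1 = hap2)), recode = FALSE)
  t2 <- build_psi_star_tensor(cohort2, "S01", ws,
                              partners = cohort2$samples[-1])
  expect_equal(t2$A, tensor$A)
  expect_equal(t2$B, tensor$B)
})

test_that("windows without focal-het SNPs are flagged unusable, not fatal", {
  hap <- rbind(c(1L, 1L), c(1L, 1L),   # focal homozygous everywhere
               c(0L, 1L), c(1L, 0L),
               c(0L, 0L), c(1L, 1L))
  cohort <- cohort_from_matrices(list(chr1 = hap), maf = 0.5)
  ws <- whole_chrom_window(cohort)
  expect_message(
    tensor <- build_psi_star_tensor(cohort, "S01", ws,
                                    partners = c("S02", "S03")),
    "no focal-het")
  expect_false(tensor$usable[1])
  expect_true(all(tensor$A == 0))
})
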