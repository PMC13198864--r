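test_that("founder alleles follow the configured frequencies and seed", {
  cfg <- sim_config(seed = 71, n_unrelated = 25, n_chromosomes = 1,
                    snps_per_chrom = 400, maf_range = c(0.5, 0.5))
  fnd <- simulate_founders(cfg)
  expect_equal(dim(fnd$haplotypes$chr1), c(50, 400))
  expect_equal(mean(fnd$haplotypes$chr1), 0.5, tolerance = 0.02)  # 20k draws
  # bit-identical under the same seed
  fnd2 <- simulate_founders(cfg)
  expect_identical(fnd$haplotypes, fnd2$haplotypes)
})

test_that("two founder populations diverge by the configured amount", {
  cfg <- sim_config(seed = 72, n_unrelated = 400, n_chromosomes = 1,
                    snps_per_chrom = 300, subpop = list(fst = 0.15))
  fnd <- simulate_founders(cfg)
  h <- fnd$haplotypes$chr1
  rows_of <- function(pop) {
    idx <- which(fnd$pop == pop)
    sort(c(2 * idx - 1, 2 * idx))
  }
  f1 <- colMeans(h[rows_of(1), ]); f2 <- colMeans(h[rows_of(2), ])
  # Balding-Nichols: Var(p1 - p2) = 2 * F * p * (1 - p)
  p <- fnd$maf[[1]]
  expect_equal(mean((f1 - f2)^2), mean(2 * 0.15 * p * (1 - p)),
               tolerance = 0.25)
  # and an unstratified config shows no such divergence
  cfg0 <- sim_config(seed = 72, n_unrelated = 400, n_chromosomes = 1,
                     snps_per_chrom = 300)
  fnd0 <- simulate_founders(cfg0)
  h0 <- fnd0$haplotypes$chr1
  d0 <- colMeans(h0[rows_of(1), ]) - colMeans(h0[rows_of(2), ])
  expect_lt(mean(d0^2), 0.5 * mean((f1 - f2)^2))
})

test_that("meiosis alternates parental haplotypes at map-driven crossovers", {
  set.seed(73)
  hapA <- rep(0L, 200); hapB <- rep(1L, 200)
  # zero genetic length -> no crossovers, gamete is one whole parental hap
  g0 <- meiosis(hapA, hapB, rep(0, 200))
  expect_length(g0$crossovers, 0)
  expect_true(all(g0$gamete == 0L) || all(g0$gamete == 1L))
  # 100 cM -> one expected crossover per meiosis
  cM <- seq(0, 100, length.out = 200)
  n_cross <- replicate(2000, length(meiosis(hapA, hapB, cM)$crossovers))
  expect_equal(mean(n_cross), 1, tolerance = 0.1)
  # gamete tracks the reported origins exactly
  g <- meiosis(hapA, hapB, cM)
  expect_equal(g$gamete, ifelse(g$origin == 1L, hapA, hapB))
})

test_that("simulated kinship matches pedigree expectations", {
  # a long genome keeps the realized-kinship variance small enough that
  # single relatives land near their pedigree expectations
  set.seed(74)
  cfg <- sim_config(n_focal = 1, include_parents = TRUE,
                    relatives_per_focal = c(second = 1, third = 1),
                    n_unrelated = 60, n_chromosomes = 10,
                    snps_per_chrom = 1000, chrom_length_cM = 120)
  sim <- qc_filter_sim(simulate_cohort(cfg))
  f <- sim$focal_ids[1]
  p <- pihat_all(sim$cohort, f)
  expect_equal(unname(p[paste0(f, ".p1")]), 0.5, tolerance = 0.2)
  expect_equal(unname(p[paste0(f, ".p2")]), 0.5, tolerance = 0.2)
  expect_equal(unname(p[paste0(f, ".r1")]), 0.25, tolerance = 0.5)
  expect_equal(unname(p[paste0(f, ".r2")]), 0.125, tolerance = 0.8)
  expect_lt(max(abs(p[grep("^U", names(p))])), 0.12)
})

test_that("every simulated trio is Mendelian-consistent and truth agrees", {
  set.seed(75)
  cfg <- sim_config(n_focal = 3, n_unrelated = 10, n_chromosomes = 2,
                    snps_per_chrom = 500)
  sim <- simulate_cohort(cfg)
  g <- diploid_genotypes(sim$cohort)
  for (f in sim$focal_ids) {
    p1 <- sim$parents[[f]]$p1; p2 <- sim$parents[[f]]$p2
    off <- g[f, ]
    # offspring dosage must be attainable from parental dosages
    lo <- as.integer(p1 == 2) + as.integer(p2 == 2)
    hi <- 2L - as.integer(p1 == 0) - as.integer(p2 == 0)
    expect_true(all(off >= lo & off <= hi))
    # derived trio truth never contradicts the simulator's exact truth
    derived <- trio_ground_truth(sim$cohort, f, p1, p2)
    expect_false(any(derived$calls$status == "mendelian_error"))
    res <- derived$calls$status == "resolved"
    expect_equal(derived$calls$row[res],
                 sim$truth[[f]]$calls$row[res])
    expect_equal(derived$calls$origin1[res],
                 sim$truth[[f]]$calls$origin1[res])
  }
})

test_that("the whole simulation is deterministic under a seed", {
  cfg <- sim_config(seed = 76, n_focal = 1,
                    relatives_per_focal = c(second = 1),
                    n_unrelated = 15, n_chromosomes = 2, snps_per_chrom = 200,
                    switch_error_rate = 0.02)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort$haplotypes, s2$cohort$haplotypes)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$switches, s2$switches)
})

test_that("switch errors hit heterozygous sites at the requested rate", {
  set.seed(77)
  cfg <- sim_config(n_focal = 0, n_unrelated = 40, n_chromosomes = 2,
                    snps_per_chrom = 600)
  sim <- simulate_cohort(cfg)
  # rate zero is the identity
  out0 <- inject_switch_errors(sim$cohort, 0)
  expect_identical(out0$cohort$haplotypes, sim$cohort$haplotypes)
  expect_equal(nrow(out0$switches), 0)
  # diploid genotypes are untouched by switches; realized switch rate,
  # recounted independently from the haplotypes, matches the request
  rate <- 0.05
  out <- inject_switch_errors(sim$cohort, rate)
  expect_equal(diploid_genotypes(out$cohort), diploid_genotypes(sim$cohort))
  counts <- rowSums(vapply(sim$cohort$samples, function(id)
    count_switches(sim$cohort, out$cohort, id), numeric(2)))
  realized <- counts["switches"] / counts["intervals"]
  expect_equal(unname(realized), rate, tolerance = 0.25)
  expect_equal(nrow(out$switches) / counts[["intervals"]], rate,
               tolerance = 0.25)
})
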