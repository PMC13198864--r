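# One focal sample over `sites` het sites per chromosome; slot A carries
# allele 1 where `slotA_one` is TRUE.
truth_fixture <- function(slotA_one_by_chrom) {
  haps <- lapply(slotA_one_by_chrom, function(s1)
    rbind(as.integer(s1), as.integer(!s1)))
  names(haps) <- paste0("chr", seq_along(haps))
  cohort_from_matrices(haps, maf = 0.5, samples = "F1")
}

test_that("trio truth resolves transmission whenever a parent is homozygous", {
  cohort <- truth_fixture(list(rep(TRUE, 4)))
  truth <- trio_ground_truth(cohort, "F1",
                             parent1 = c(0L, 2L, 1L, 1L),
                             parent2 = c(1L, 1L, 1L, 0L))
  expect_equal(truth$calls$status,
               c("resolved", "resolved", "unresolved", "resolved"))
  # parent1 hom 0 -> allele 1 came from parent 2; hom 2 -> from parent 1
  expect_equal(truth$calls$origin1, c(2L, 1L, NA, 1L))
})

test_that("impossible parental configurations are Mendelian errors", {
  cohort <- truth_fixture(list(rep(TRUE, 3)))
  expect_warning(
    truth <- trio_ground_truth(cohort, "F1",
                               parent1 = c(0L, 2L, 1L),
                               parent2 = c(0L, 2L, 1L)),
    "Mendelian")
  expect_equal(truth$calls$status,
               c("mendelian_error", "mendelian_error", "unresolved"))
})

test_that("perfect phasing scores 100 and label flips do not matter", {
  cohort <- truth_fixture(list(rep(TRUE, 50), rep(TRUE, 50)))
  truth <- trio_ground_truth(cohort, "F1", rep(2L, 100), rep(0L, 100))
  rep1 <- acpa(cohort, truth)
  expect_equal(rep1$acpa_percent, 100)
  # globally swapping the parents in the truth leaves ACPA unchanged
  flipped <- truth
  flipped$calls$origin1 <- 3L - flipped$calls$origin1
  expect_equal(acpa(cohort, flipped)$acpa_percent, 100)
  expect_true(acpa(cohort, flipped)$orientation_used !=
              rep1$orientation_used)
})

test_that("the genome-wide score uses one global mapping; chromosomes may score 0", {
  # four equal chromosomes, correct proportions 100/88/100/0 -> 72% overall
  cohort <- truth_fixture(list(
    rep(TRUE, 100),
    rep(c(TRUE, FALSE), c(88, 12)),
    rep(TRUE, 100),
    rep(FALSE, 100)))
  truth <- trio_ground_truth(cohort, "F1", rep(2L, 400), rep(0L, 400))
  report <- acpa(cohort, truth)
  expect_equal(report$acpa_percent, 72)
  expect_equal(report$per_chromosome$acpa_percent, c(100, 88, 100, 0))
  expect_equal(report$n_scored_snps, 400L)
  expect_gte(report$acpa_percent, 50)
})

test_that("triple-het sites can be filled from the nearest resolved neighbour", {
  # sites 1,2,4 resolved; site 3 triple-het, flanked by resolved sites whose
  # slot-A alleles all trace to parent 1
  cohort <- truth_fixture(list(c(TRUE, TRUE, FALSE, TRUE)))
  p1 <- c(2L, 2L, 1L, 2L); p2 <- c(0L, 0L, 1L, 0L)
  default <- trio_ground_truth(cohort, "F1", p1, p2)
  expect_equal(default$calls$status[3], "unresolved")
  expect_equal(acpa(cohort, default)$n_scored_snps, 3L)
  filled <- trio_ground_truth(cohort, "F1", p1, p2, fill_unresolved = TRUE)
  expect_equal(filled$calls$status[3], "filled")
  # slot A at site 3 carries allele 0 while parent 1 holds slot A nearby,
  # so allele 1 at site 3 is imputed to parent 2
  expect_equal(filled$calls$origin1[3], 2L)
  expect_equal(acpa(cohort, filled)$n_scored_snps, 4L)
  expect_equal(acpa(cohort, filled)$acpa_percent, 100)
})

test_that("acpa requires resolved sites", {
  cohort <- truth_fixture(list(rep(TRUE, 3)))
  truth <- trio_ground_truth(cohort, "F1", rep(1L, 3), rep(1L, 3))
  expect_error(acpa(cohort, truth), "no resolved sites")
})

test_that("more random orientation noise never helps, in expectation", {
  set.seed(61)
  cfg <- sim_config(n_focal = 1, n_unrelated = 2, include_parents = TRUE,
                    n_chromosomes = 4, snps_per_chrom = 400)
  sim <- simulate_cohort(cfg)
  f <- sim$focal_ids[1]
  truth <- sim$truth[[f]]
  # align slot A to the paternal gamete on every chromosome first, so the
  # zero-noise phasing is perfect by construction
  base <- sim$cohort
  frows <- 2 * match(f, base$samples) - c(1, 0)
  for (ch in base$chromosomes) {
    if (sim$slotA_parent[f, ch] == 2L)
      base$haplotypes[[ch]][frows, ] <- base$haplotypes[[ch]][rev(frows), ]
  }
  flip_windows <- function(k) {
    # flip k of 8 equal chunks (2 per chromosome), score against truth
    cohort <- base
    fr <- frows
    chunks <- expand.grid(half = 1:2, chrom = cohort$chromosomes)
    sel <- sample(nrow(chunks), k)
    for (i in sel) {
      ch <- as.character(chunks$chrom[i])
      m <- ncol(cohort$haplotypes[[ch]])
      cols <- if (chunks$half[i] == 1) 1:(m %/% 2) else (m %/% 2 + 1):m
      h <- cohort$haplotypes[[ch]]
      tmp <- h[fr[1], cols]; h[fr[1], cols] <- h[fr[2], cols]; h[fr[2], cols] <- tmp
      cohort$haplotypes[[ch]] <- h
    }
    acpa(cohort, truth)$acpa_percent
  }
  mean_at <- vapply(c(0, 2, 4), function(k)
    mean(replicate(40, flip_windows(k))), numeric(1))
  expect_equal(mean_at[1], 100)
  expect_true(all(diff(mean_at) < 0))
})

test_that("relatedness strata are binned at canonical midpoints", {
  set.seed(62)
  cfg <- sim_config(n_focal = 4,
                    relatives_per_focal = c(rep(list(c(second = 1)), 2),
                                            rep(list(c(second = 0)), 2)),
                    n_unrelated = 40, n_chromosomes = 4, snps_per_chrom = 1000)
  sim <- qc_filter_sim(simulate_cohort(cfg))
  reports <- lapply(sim$focal_ids, function(f) {
    r <- list(acpa_percent = if (f %in% sim$focal_ids[1:2]) 99 else 80,
              focal = f)
    class(r) <- "acpa_report"
    r
  })
  tab <- stratify_by_relatedness(reports, sim$cohort)
  expect_true("2nd degree" %in% tab$stratum)
  expect_equal(sum(tab$n), 4)
  expect_gt(tab$mean_acpa[tab$stratum == "2nd degree"],
            max(tab$mean_acpa[tab$stratum != "2nd degree"]))
  # empty input gives an empty table
  expect_equal(nrow(stratify_by_relatedness(list(), sim$cohort)), 0)
})
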