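# Independent reference implementations used as oracles; deliberately
# brute-force and separate from the package's code paths.

# psi-hat by exhaustive enumeration of all contiguous runs of identical
# alleles at focal-het sites: select by (length, then score, then leftmost)
# and return the selected run's score.
psi_oracle <- function(focal_hap, other_hap, het_mask, maf, exponent = 1 / 5) {
  x <- focal_hap[het_mask]
  y <- other_hap[het_mask]
  p <- maf[het_mask]
  L <- length(x)
  if (L == 0) return(0)
  term <- ((x - p) * (y - p) / (p * (1 - p)))^exponent
  best <- c(len = 0, sum = 0)
  for (i in seq_len(L)) for (j in i:L) {
    if (all(x[i:j] == y[i:j])) {
      len <- j - i + 1
      s <- sum(term[i:j])
      if (len > best["len"] ||
          (len == best["len"] && s > best["sum"] + 1e-12)) {
        best <- c(len = len, sum = s)
      }
    }
  }
  unname(best["sum"])
}

# Pairwise lambda matrix straight from the definition.
lambda_matrix_oracle <- function(A, B) {
  W <- nrow(A)
  lam <- matrix(NA_real_, W, W)
  for (g in seq_len(W - 1)) for (h in (g + 1):W) {
    lam[g, h] <- lam[h, g] <-
      cor(A[g, ], A[h, ]) - cor(A[g, ], B[h, ]) -
      cor(B[g, ], A[h, ]) + cor(B[g, ], B[h, ])
  }
  lam
}

# Exhaustive orientation search: maximize sum over pairs of
# o_g * o_h * lambda_gh with o_1 fixed to +1. Returns the optimal
# orientations and the margin to the runner-up.
exhaustive_orientations <- function(lam) {
  W <- nrow(lam)
  stopifnot(W <= 16)
  configs <- as.matrix(expand.grid(rep(list(c(1, -1)), W - 1)))
  scores <- apply(configs, 1, function(o_rest) {
    o <- c(1, o_rest)
    s <- 0
    for (g in seq_len(W - 1)) for (h in (g + 1):W)
      s <- s + o[g] * o[h] * lam[g, h]
    s
  })
  ord <- order(scores, decreasing = TRUE)
  list(orientation = c(1, configs[ord[1], ]),
       margin = scores[ord[1]] - scores[ord[2]])
}

# Tensor with a planted two-profile structure: window w's A vector follows
# the "parent 1" profile when the true orientation is +1, else the
# "parent 2" profile. Windows live on distinct chromosomes.
planted_tensor <- function(W, P, noise = 0.2, prob_flip = 0.5) {
  u <- rnorm(P); v <- rnorm(P)
  truth <- ifelse(runif(W) < prob_flip, -1, 1)
  A <- matrix(0, W, P); B <- matrix(0, W, P)
  for (w in seq_len(W)) {
    a <- if (truth[w] == 1) u else v
    b <- if (truth[w] == 1) v else u
    A[w, ] <- a + rnorm(P, sd = noise)
    B[w, ] <- b + rnorm(P, sd = noise)
  }
  windows <- data.frame(chrom = paste0("chr", seq_len(W)),
                        start_bp = 0, end_bp = 1, start_cM = 0, end_cM = 50,
                        span_cM = 50, window = seq_len(W),
                        snp_start = 1L, snp_end = 1L, n_snps = 1L,
                        stringsAsFactors = FALSE)
  class(windows) <- c("window_set", "data.frame")
  tensor <- structure(list(focal = "F", partners = paste0("P", seq_len(P)),
                           excluded = character(0), windows = windows,
                           A = A, B = B, usable = rep(TRUE, W)),
                      class = "psi_star_tensor")
  list(tensor = tensor, truth = truth)
}

# Standard switch-error counter: compares an individual's haplotypes before
# and after perturbation and counts phase switches along heterozygous sites.
count_switches <- function(orig, mod, sample_id) {
  rows <- 2 * match(sample_id, orig$samples) - c(1, 0)
  total_switches <- 0
  total_intervals <- 0
  for (ch in orig$chromosomes) {
    ho <- orig$haplotypes[[ch]][rows, , drop = FALSE]
    hm <- mod$haplotypes[[ch]][rows, , drop = FALSE]
    het <- which(ho[1, ] != ho[2, ])
    if (length(het) < 1) next
    state <- as.integer(hm[1, het] != ho[1, het])
    total_switches <- total_switches + state[1] + sum(abs(diff(state)))
    total_intervals <- total_intervals + length(het)
  }
  c(switches = total_switches, intervals = total_intervals)
}

# Simulated trio scored under per-site random assignment: returns the ACPA
# of the focal individual after flipping each site's slot pair with
# probability one half.
random_assignment_acpa <- function(cohort, truth) {
  fr <- 2 * match(truth$focal, cohort$samples) - c(1, 0)
  scrambled <- cohort
  for (ch in cohort$chromosomes) {
    h <- scrambled$haplotypes[[ch]]
    flip <- which(runif(ncol(h)) < 0.5)
    tmp <- h[fr[1], flip]
    h[fr[1], flip] <- h[fr[2], flip]
    h[fr[2], flip] <- tmp
    scrambled$haplotypes[[ch]] <- h
  }
  acpa(scrambled, truth)$acpa_percent
}
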