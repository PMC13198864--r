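#' Signed cross-window haplotype correlation (lambda)
#'
#' Combines the four Pearson correlations between two windows' psi-star
#' profile pairs into a single signed score:
#' `r(A_g, A_h) - r(A_g, B_h) - r(B_g, A_h) + r(B_g, B_h)`.
#' A positive lambda indicates that haplotype A of window g and haplotype A
#' of window h descend from the same parent; a negative lambda indicates
#' they cross. Range `[-4, 4]`; relabelling one window's A/B flips the sign
#' exactly.
#'
#' @param vecs_g,vecs_h lists with numeric components `A` and `B`: the two
#'   psi-star vectors of each window over a shared partner axis.
#' @return numeric scalar, or `NA` if any vector has zero variance (the
#'   pair is then undefined and should be skipped).
#' @export
lambda_pair <- function(vecs_g, vecs_h) {
  if (var(vecs_g$A) == 0 || var(vecs_g$B) == 0 ||
      var(vecs_h$A) == 0 || var(vecs_h$B) == 0) return(NA_real_)
  cor(vecs_g$A, vecs_h$A) - cor(vecs_g$A, vecs_h$B) -
    cor(vecs_g$B, vecs_h$A) + cor(vecs_g$B, vecs_h$B)
}

#' Same-chromosome adjustment of lambda
#'
#' A negative lambda between two windows of the same chromosome implies a
#' switch error between them; since switch errors occur with frequency below
#' one half, such evidence is down-weighted by `penalty` (default 0.75).
#' Positive values and cross-chromosome pairs are untouched.
#'
#' @param lam raw lambda value.
#' @param same_chromosome logical.
#' @param penalty multiplicative factor applied when `lam < 0` on the same
#'   chromosome; `1.0` disables the adjustment.
#' @return adjusted lambda.
#' @export
adjusted_lambda <- function(lam, same_chromosome, penalty = 0.75) {
  ifelse(!is.na(lam) & lam < 0 & same_chromosome, penalty * lam, lam)
}

#' Greedily merge windows into two genome-wide parental sets
#'
#' Computes the adjusted lambda for every unordered window pair, seeds with
#' the pair of maximal absolute value (first window fixed to orientation +1,
#' second set by the sign), then repeatedly picks the unassigned window with
#' the largest absolute adjusted lambda against the merged group's
#' aggregated psi-star vectors (element-wise sums over members, aligned by
#' orientation) and folds it in with the sign's orientation. Greedy with no
#' backtracking; ties broken by lowest window index. The same-chromosome
#' penalty applies to a window-vs-group lambda when the window shares a
#' chromosome with at least one group member. Unusable windows (no
#' focal-het SNP or zero-variance profiles) receive orientation +1 and an
#' `uninformative` flag.
#'
#' @param tensor a `psi_star_tensor` from [build_psi_star_tensor()].
#' @param penalty same-chromosome negative-lambda penalty
#'   (see [adjusted_lambda()]).
#' @return A `phasing_result`: list with `orientation` (+1/-1 per window,
#'   +1 meaning the window's A haplotype joins parental set 1),
#'   `uninformative` (logical per window), `merge_log` (data.frame of merge
#'   decisions), and the window table.
#' @export
greedy_phase <- function(tensor, penalty = 0.75) {
  windows <- tensor$windows
  W <- nrow(windows)
  if (W < 2L) stop("greedy_phase: need >= 2 windows")
  rv <- function(m) apply(m, 1L, var)
  usable <- tensor$usable & rv(tensor$A) > 0 & rv(tensor$B) > 0
  if (sum(usable) < 2L) stop("greedy_phase: fewer than 2 usable windows")

  # all pairwise correlations at once: rows 2w-1 / 2w are window w's A / B
  X <- matrix(0, 2L * W, ncol(tensor$A))
  X[seq(1L, 2L * W, 2L), ] <- tensor$A
  X[seq(2L, 2L * W, 2L), ] <- tensor$B
  C <- suppressWarnings(cor(t(X)))
  ai <- function(w) 2L * w - 1L
  bi <- function(w) 2L * w
  lam_raw <- matrix(NA_real_, W, W)
  uw <- which(usable)
  for (g in uw) for (h in uw) if (g < h)
    lam_raw[g, h] <- C[ai(g), ai(h)] - C[ai(g), bi(h)] -
      C[bi(g), ai(h)] + C[bi(g), bi(h)]
  same <- outer(windows$chrom, windows$chrom, "==")
  lam_adj <- adjusted_lambda(lam_raw, same, penalty)
  if (all(is.na(lam_adj))) stop("greedy_phase: all pairwise lambda undefined")

  orientation <- rep(NA_integer_, W)
  log_rows <- list()
  # seed: maximal |adjusted lambda|; ties by lowest (g, h)
  abs_adj <- abs(lam_adj)
  best <- max(abs_adj, na.rm = TRUE)
  cand <- which(abs_adj == best, arr.ind = TRUE)
  cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
  g <- cand[1L, 1L]; h <- cand[1L, 2L]
  sgn <- if (!is.na(lam_raw[g, h]) && lam_raw[g, h] < 0) -1L else 1L
  orientation[g] <- 1L; orientation[h] <- sgn
  log_rows[[1L]] <- data.frame(step = 1L, window = h, against = g,
                               lambda = lam_raw[g, h],
                               adjusted_lambda = lam_adj[g, h], sign = sgn)
  side1 <- tensor$A[g, ] + (if (sgn == 1L) tensor$A[h, ] else tensor$B[h, ])
  side2 <- tensor$B[g, ] + (if (sgn == 1L) tensor$B[h, ] else tensor$A[h, ])
  members <- c(g, h)
  step <- 1L
  repeat {
    rest <- which(usable & is.na(orientation))
    if (length(rest) == 0L) break
    lam_w <- vapply(rest, function(w)
      lambda_pair(list(A = side1, B = side2),
                  list(A = tensor$A[w, ], B = tensor$B[w, ])), numeric(1))
    same_w <- windows$chrom[rest] %in% windows$chrom[members]
    adj_w <- adjusted_lambda(lam_w, same_w, penalty)
    if (all(is.na(adj_w))) {
      warning("greedy_phase: remaining windows have undefined lambda; ",
              "marked uninformative")
      usable[rest] <- FALSE
      break
    }
    k <- which(abs(adj_w) == max(abs(adj_w), na.rm = TRUE))[1L]
    w <- rest[k]
    sgn <- if (!is.na(lam_w[k]) && lam_w[k] < 0) -1L else 1L
    orientation[w] <- sgn
    step <- step + 1L
    log_rows[[step]] <- data.frame(step = step, window = w, against = NA_integer_,
                                   lambda = lam_w[k],
                                   adjusted_lambda = adj_w[k], sign = sgn)
    side1 <- side1 + (if (sgn == 1L) tensor$A[w, ] else tensor$B[w, ])
    side2 <- side2 + (if (sgn == 1L) tensor$B[w, ] else tensor$A[w, ])
    members <- c(members, w)
  }
  uninformative <- !usable
  orientation[is.na(orientation)] <- 1L
  structure(list(orientation = orientation, uninformative = uninformative,
                 merge_log = do.call(rbind, log_rows), windows = windows,
                 focal = tensor$focal),
            class = "phasing_result")
}

#' @export
print.phasing_result <- function(x, ...) {
  cat("phasing_result: focal", x$focal, "-", length(x$orientation),
      "windows,", sum(x$uninformative), "uninformative\n")
  invisible(x)
}

#' Apply a phasing result to the focal individual's haplotypes
#'
#' Swaps the focal individual's two haplotype slots within every window of
#' orientation -1, so that slot A carries parental set 1 on every chromosome.
#' Within-window sequences are untouched. This is a single-use transform:
#' applying the same result twice re-swaps the windows.
#'
#' @param cohort a [phased_cohort()].
#' @param focal focal sample id.
#' @param state a `phasing_result` from [greedy_phase()].
#' @return The cohort with the focal individual's slots rewritten.
#' @export
apply_orientation <- function(cohort, focal, state) {
  fr <- hap_rows(cohort, focal)
  windows <- state$windows
  for (w in which(state$orientation == -1L)) {
    ch <- windows$chrom[w]
    offset <- min(which(cohort$variants$chrom == ch)) - 1L
    cols <- (windows$snp_start[w]:windows$snp_end[w]) - offset
    h <- cohort$haplotypes[[ch]]
    tmp <- h[fr[1L], cols]
    h[fr[1L], cols] <- h[fr[2L], cols]
    h[fr[2L], cols] <- tmp
    cohort$haplotypes[[ch]] <- h
  }
  cohort
}
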