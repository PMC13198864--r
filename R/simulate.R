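#' Simulation configuration
#'
#' Defines a synthetic phased cohort: founder allele frequencies, a genetic
#' map with planted recombination hotspots, focal trio offspring with
#' configurable distant relatives, unrelated fill, optional two-subpopulation
#' founder structure, and within-chromosome switch-error injection.
#'
#' @param seed integer RNG seed (`NULL` uses the current RNG state).
#' @param n_focal number of focal trio offspring.
#' @param relatives_per_focal named integer vector `c(second=, third=,
#'   fourth=)` of distant relatives planted per focal individual, or a list
#'   of such vectors (one per focal). 2nd degree = avuncular, 3rd = first
#'   cousin, 4th = first cousin once removed; relatives alternate between
#'   the paternal and maternal side.
#' @param n_unrelated unrelated founders added to the cohort.
#' @param include_parents keep the focal individuals' parents in the
#'   analysis cohort (they are always retained separately for truth).
#' @param n_chromosomes,snps_per_chrom,chrom_length_cM genome dimensions;
#'   physical length is 1 Mb per cM.
#' @param maf_range founder minor-allele-frequency distribution, uniform on
#'   this interval.
#' @param n_hotspots,hotspot_intensity planted recombination hotspots per
#'   chromosome and the range of their cM/Mb intensity multipliers over the
#'   background rate.
#' @param switch_error_rate per-heterozygous-site probability of a
#'   within-chromosome switch error, injected into every cohort member.
#' @param subpop `NULL`, or `list(fst = )`: two founder populations with
#'   Balding-Nichols allele-frequency divergence; the two parents of each
#'   focal individual (and the corresponding founder lineages) are drawn
#'   from different populations, and unrelated fill is split between them.
#' @param founder_pool_size `NULL` for independent founder sites (default),
#'   or a pool size H: founder haplotypes become recombinant mosaics of H
#'   base haplotypes, giving the founders LD blocks.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = NULL, n_focal = 1,
                       relatives_per_focal = c(second = 0, third = 0, fourth = 0),
                       n_unrelated = 50, include_parents = FALSE,
                       n_chromosomes = 2, snps_per_chrom = 200,
                       chrom_length_cM = 100, maf_range = c(0.05, 0.5),
                       n_hotspots = 10, hotspot_intensity = c(15, 30),
                       switch_error_rate = 0, subpop = NULL,
                       founder_pool_size = NULL) {
  norm_rel <- function(r) {
    out <- c(second = 0L, third = 0L, fourth = 0L)
    out[names(r)] <- as.integer(r)
    if (any(out < 0)) stop("relative counts must be >= 0")
    out
  }
  rel <- if (is.list(relatives_per_focal)) {
    if (length(relatives_per_focal) != n_focal)
      stop("relatives_per_focal list must have one element per focal")
    lapply(relatives_per_focal, norm_rel)
  } else rep(list(norm_rel(relatives_per_focal)), n_focal)
  stopifnot(n_focal >= 0, n_unrelated >= 0, n_chromosomes >= 1,
            snps_per_chrom >= 2, chrom_length_cM > 0,
            switch_error_rate >= 0, switch_error_rate < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  structure(list(seed = seed, n_focal = n_focal, relatives = rel,
                 n_unrelated = n_unrelated, include_parents = include_parents,
                 n_chromosomes = n_chromosomes, snps_per_chrom = snps_per_chrom,
                 chrom_length_cM = chrom_length_cM, maf_range = maf_range,
                 n_hotspots = n_hotspots, hotspot_intensity = hotspot_intensity,
                 switch_error_rate = switch_error_rate, subpop = subpop,
                 founder_pool_size = founder_pool_size),
            class = "sim_config")
}

#' Simulate a genetic map with planted hotspots
#'
#' Each chromosome gets evenly spaced anchor points; `n_hotspots` randomly
#' chosen inter-anchor intervals receive a cM/Mb rate multiplier drawn from
#' `hotspot_intensity`, and the cumulative cM is rescaled so each chromosome
#' spans exactly `chrom_length_cM`.
#'
#' @param config a [sim_config()].
#' @return A [genetic_map()].
#' @export
simulate_genetic_map <- function(config) {
  n_anchor <- 41L
  maps <- lapply(seq_len(config$n_chromosomes), function(c_i) {
    len_bp <- config$chrom_length_cM * 1e6
    pos <- round(seq(1, len_bp, length.out = n_anchor))
    rate <- rep(1, n_anchor - 1L)
    hot <- sample.int(n_anchor - 1L, min(config$n_hotspots, n_anchor - 1L))
    rate[hot] <- runif(length(hot), config$hotspot_intensity[1],
                       config$hotspot_intensity[2])
    inc <- rate * diff(pos) / 1e6
    cM <- c(0, cumsum(inc))
    cM <- cM * config$chrom_length_cM / cM[n_anchor]
    data.frame(chrom = paste0("chr", c_i), pos = pos, cM = cM,
               stringsAsFactors = FALSE)
  })
  genetic_map(do.call(rbind, maps))
}

# Draw one founder haplotype for one chromosome, either site-independent
# at frequencies p or as a recombinant mosaic of a base-haplotype pool.
draw_hap <- function(p, pool = NULL, cM = NULL) {
  m <- length(p)
  if (is.null(pool)) return(rbinom(m, 1L, p))
  len <- cM[m] - cM[1]
  n_cross <- rpois(1L, 3 * len / 100)
  breaks <- sort(runif(n_cross, cM[1], cM[m]))
  seg <- findInterval(cM, breaks) + 1L
  rows <- sample.int(nrow(pool), length(breaks) + 1L, replace = TRUE)
  pool[cbind(rows[seg], seq_len(m))]
}

#' Simulate founder haplotypes
#'
#' Draws `n` founders whose haplotype alleles are independent Bernoulli
#' draws at each SNP's configured allele frequency (per subpopulation when
#' the config defines one; founders then alternate between the two
#' populations).
#'
#' @param config a [sim_config()]; its seed is applied if set.
#' @param n number of founders (default `config$n_unrelated`).
#' @return list with `haplotypes` (per chromosome, a `2n x m` 0/1 matrix,
#'   rows 2i-1/2i = founder i), `maf` (the generating frequencies, per
#'   chromosome, for population 1 when stratified), and `pop` (per-founder
#'   population index, 0 = unstratified).
#' @export
simulate_founders <- function(config, n = config$n_unrelated) {
  if (!is.null(config$seed)) set.seed(config$seed)
  freqs <- sim_frequencies(config)
  pop <- if (is.null(config$subpop)) rep(0L, n) else rep_len(c(1L, 2L), n)
  haps <- lapply(seq_len(config$n_chromosomes), function(c_i) {
    h <- matrix(0L, 2L * n, config$snps_per_chrom)
    for (i in seq_len(n)) {
      p <- freqs$p[[max(pop[i], 1L)]][[c_i]]
      h[2L * i - 1L, ] <- draw_hap(p)
      h[2L * i, ] <- draw_hap(p)
    }
    h
  })
  names(haps) <- paste0("chr", seq_len(config$n_chromosomes))
  list(haplotypes = haps, maf = freqs$p[[1L]], pop = pop)
}

# Generating allele frequencies: base p per SNP; under subpop structure two
# Balding-Nichols draws around the base frequency.
sim_frequencies <- function(config) {
  base <- lapply(seq_len(config$n_chromosomes), function(c_i)
    runif(config$snps_per_chrom, config$maf_range[1], config$maf_range[2]))
  if (is.null(config$subpop)) return(list(p = list(base, base), base = base))
  f <- config$subpop$fst
  stopifnot(f > 0, f < 1)
  bn <- function(p) pmin(pmax(rbeta(length(p), p * (1 - f) / f,
                                    (1 - p) * (1 - f) / f), 0.01), 0.99)
  list(p = list(lapply(base, bn), lapply(base, bn)), base = base)
}

#' Simulate one meiosis
#'
#' Crossover count is Poisson with mean `length_cM / 100` (no interference),
#' crossover positions uniform on the cM axis, and the starting haplotype is
#' chosen by a fair coin; the gamete alternates between the parental
#' haplotypes at each crossover.
#'
#' @param hapA,hapB the parent's two haplotypes (0/1 vectors) for one
#'   chromosome.
#' @param cM SNP genetic positions (non-decreasing).
#' @return list with `gamete` (0/1 vector), `origin` (1 = from `hapA`,
#'   2 = from `hapB`, per SNP), and `crossovers` (cM positions).
#' @export
meiosis <- function(hapA, hapB, cM) {
  m <- length(hapA)
  stopifnot(length(hapB) == m, length(cM) == m)
  len <- cM[m] - cM[1]
  n_cross <- rpois(1L, len / 100)
  breaks <- sort(runif(n_cross, cM[1], cM[m]))
  start <- sample.int(2L, 1L)
  origin <- (start - 1L + findInterval(cM, breaks)) %% 2L + 1L
  gamete <- ifelse(origin == 1L, hapA, hapB)
  list(gamete = as.integer(gamete), origin = origin, crossovers = breaks)
}

# Internal individual representation: list per chromosome of a 2 x m matrix
# (row 1 = haplotype inherited from parent 1, row 2 = from parent 2; for
# founders the two rows are independent draws).
sim_child <- function(p1, p2, cM_list) {
  lapply(seq_along(cM_list), function(c_i) {
    g1 <- meiosis(p1[[c_i]][1L, ], p1[[c_i]][2L, ], cM_list[[c_i]])$gamete
    g2 <- meiosis(p2[[c_i]][1L, ], p2[[c_i]][2L, ], cM_list[[c_i]])$gamete
    rbind(g1, g2)
  })
}

sim_founder_ind <- function(freq_pop, pool = NULL, cM_list = NULL) {
  lapply(seq_along(freq_pop), function(c_i)
    rbind(draw_hap(freq_pop[[c_i]], pool[[c_i]], cM_list[[c_i]]),
          draw_hap(freq_pop[[c_i]], pool[[c_i]], cM_list[[c_i]])))
}

#' Simulate a phased cohort with known parental origin
#'
#' Builds founder haplotypes, a hotspot-bearing genetic map, focal trio
#' offspring with the configured distant relatives (via hidden grandparent
#' lineages), and unrelated fill; transmits haplotypes through map-driven
#' meioses ([meiosis()]); scrambles each individual's per-chromosome
#' haplotype slot order (within-chromosome phase labels carry no
#' cross-chromosome meaning, as after real within-chromosome phasing);
#' recodes alleles so code 1 is the cohort minor allele; and finally injects
#' switch errors at the configured rate. Parental genotypes and exact
#' parental-origin truth are recorded before error injection.
#'
#' @param config a [sim_config()].
#' @return A `sim_cohort`: list with `cohort` (the analysis
#'   [phased_cohort()]), `map`, `pedigree` (data.frame: id, role, focal,
#'   pop), `focal_ids`, `parents` (per focal: diploid dosage vectors `p1`,
#'   `p2` on the final allele coding), `truth` (per focal: exact
#'   `trio_truth` with every focal-het site resolved), `slotA_parent`
#'   (focal x chromosome matrix: which parent's gamete sits in slot A
#'   before error injection), `switches` (injected switch-error table), and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  C <- config$n_chromosomes
  chroms <- paste0("chr", seq_len(C))
  map <- simulate_genetic_map(config)
  freqs <- sim_frequencies(config)
  # SNP positions on the physical axis, genetic positions from the map
  positions <- lapply(chroms, function(ch) {
    s <- map[map$chrom == ch, ]
    span <- s$pos[nrow(s)] - s$pos[1] + 1
    sort(sample.int(span, config$snps_per_chrom)) + s$pos[1] - 1
  })
  cM_list <- lapply(seq_len(C), function(c_i)
    interpolate_genetic_position(map, chroms[c_i], positions[[c_i]]))
  pool <- NULL
  if (!is.null(config$founder_pool_size)) {
    pool <- lapply(seq_len(C), function(c_i) {
      H <- config$founder_pool_size
      t(vapply(seq_len(H), function(i) rbinom(config$snps_per_chrom, 1L,
                                              freqs$p[[1L]][[c_i]]),
               integer(config$snps_per_chrom)))
    })
  }
  pop_freq <- function(pop) freqs$p[[max(pop, 1L)]]
  founder <- function(pop) sim_founder_ind(pop_freq(pop), pool, cM_list)

  inds <- list(); ped <- list()
  add <- function(ind, id, role, focal = NA_character_, pop = 0L) {
    inds[[id]] <<- ind
    ped[[length(ped) + 1L]] <<- data.frame(id = id, role = role, focal = focal,
                                           pop = pop, stringsAsFactors = FALSE)
  }
  in_cohort <- character(0)
  parents_raw <- list()
  focal_ids <- sprintf("F%03d", seq_len(config$n_focal))
  for (i in seq_along(focal_ids)) {
    fid <- focal_ids[i]
    rel <- config$relatives[[i]]
    rel_list <- rep(c("second", "third", "fourth"), rel)
    side_of <- ((seq_along(rel_list) - 1L) %% 2L) + 1L
    pops <- if (is.null(config$subpop)) c(0L, 0L) else c(1L, 2L)
    par_inds <- list(); gp <- list()
    for (s in 1:2) {
      if (any(side_of == s)) {
        gp[[s]] <- list(founder(pops[s]), founder(pops[s]))
        par_inds[[s]] <- sim_child(gp[[s]][[1L]], gp[[s]][[2L]], cM_list)
      } else {
        par_inds[[s]] <- founder(pops[s])
      }
    }
    foc <- sim_child(par_inds[[1L]], par_inds[[2L]], cM_list)
    add(foc, fid, "focal", fid, if (is.null(config$subpop)) 0L else 3L)
    in_cohort <- c(in_cohort, fid)
    for (s in 1:2) {
      pid <- paste0(fid, ".p", s)
      add(par_inds[[s]], pid, "parent", fid, pops[s])
      if (config$include_parents) in_cohort <- c(in_cohort, pid)
    }
    parents_raw[[fid]] <- par_inds
    for (j in seq_along(rel_list)) {
      s <- side_of[j]
      kind <- rel_list[j]
      rid <- paste0(fid, ".r", j)
      avunc <- sim_child(gp[[s]][[1L]], gp[[s]][[2L]], cM_list)
      ind <- switch(kind,
        second = avunc,
        third = sim_child(avunc, founder(pops[s]), cM_list),
        fourth = sim_child(sim_child(avunc, founder(pops[s]), cM_list),
                           founder(pops[s]), cM_list))
      add(ind, rid, kind, fid, pops[s])
      in_cohort <- c(in_cohort, rid)
    }
  }
  if (config$n_unrelated > 0) {
    upop <- if (is.null(config$subpop)) rep(0L, config$n_unrelated)
            else rep_len(c(1L, 2L), config$n_unrelated)
    for (u in seq_len(config$n_unrelated)) {
      uid <- sprintf("U%04d", u)
      add(founder(upop[u]), uid, "unrelated", NA_character_, upop[u])
      in_cohort <- c(in_cohort, uid)
    }
  }

  # per-chromosome slot scrambling (within-chromosome labels are arbitrary)
  slotA_parent <- matrix(NA_integer_, length(focal_ids), C,
                         dimnames = list(focal_ids, chroms))
  for (id in in_cohort) {
    swap <- runif(C) < 0.5
    for (c_i in which(swap)) inds[[id]][[c_i]] <- inds[[id]][[c_i]][2:1, ]
    if (id %in% focal_ids) slotA_parent[id, ] <- ifelse(swap, 2L, 1L)
  }

  # assemble the cohort, then recode alleles so code 1 is the cohort minor
  # allele; the same flips apply to the out-of-cohort parents
  variants <- do.call(rbind, lapply(seq_len(C), function(c_i)
    data.frame(chrom = chroms[c_i],
               id = paste0(chroms[c_i], ":", positions[[c_i]]),
               pos = positions[[c_i]], ref = "A", alt = "C",
               cM = cM_list[[c_i]], stringsAsFactors = FALSE)))
  haps <- list(); flip <- list()
  for (c_i in seq_len(C)) {
    h <- do.call(rbind, lapply(in_cohort, function(id) inds[[id]][[1L]]))
    for (id in in_cohort) inds[[id]][[1L]] <- NULL   # free as we go
    fl <- colMeans(h) > 0.5
    if (any(fl)) h[, fl] <- 1L - h[, fl]
    haps[[chroms[c_i]]] <- h
    flip[[c_i]] <- fl
  }
  cohort <- phased_cohort(in_cohort, variants, haps)
  cohort <- compute_allele_frequencies(cohort, recode = FALSE)

  parents <- lapply(setNames(focal_ids, focal_ids), function(fid) {
    p <- lapply(1:2, function(s) {
      ind <- parents_raw[[fid]][[s]]
      unlist(lapply(seq_len(C), function(c_i) {
        dos <- colSums(ind[[c_i]])
        dos[flip[[c_i]]] <- 2L - dos[flip[[c_i]]]
        dos
      }))
    })
    list(p1 = as.integer(p[[1L]]), p2 = as.integer(p[[2L]]))
  })

  # exact parental-origin truth at focal-het sites (before switch errors)
  offsets <- c(0L, cumsum(lengths(positions)))
  truth <- lapply(setNames(focal_ids, focal_ids), function(fid) {
    fr <- hap_rows(cohort, fid)
    calls <- do.call(rbind, lapply(seq_len(C), function(c_i) {
      h <- cohort$haplotypes[[chroms[c_i]]]
      het <- which(h[fr[1L], ] != h[fr[2L], ])
      if (length(het) == 0L) return(NULL)
      slot_with_1 <- ifelse(h[fr[1L], het] == 1L, 1L, 2L)
      sp <- slotA_parent[fid, c_i]
      origin1 <- ifelse(slot_with_1 == 1L, sp, 3L - sp)
      data.frame(row = het + offsets[c_i], chrom = chroms[c_i],
                 status = "resolved",
                 origin1 = as.integer(origin1), stringsAsFactors = FALSE)
    }))
    structure(list(focal = fid, calls = calls), class = "trio_truth")
  })

  switches <- NULL
  if (config$switch_error_rate > 0) {
    inj <- inject_switch_errors(cohort, config$switch_error_rate)
    cohort <- inj$cohort
    switches <- inj$switches
  }
  structure(list(cohort = cohort, map = map,
                 pedigree = do.call(rbind, ped), focal_ids = focal_ids,
                 parents = parents, truth = truth,
                 slotA_parent = slotA_parent, switches = switches,
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", n_samples(x$cohort), "samples,",
      length(x$focal_ids), "focal;", n_variants(x$cohort), "SNPs on",
      length(x$cohort$chromosomes), "chromosome(s)\n")
  invisible(x)
}

#' Inject within-chromosome switch errors
#'
#' At each heterozygous site of each selected individual, with probability
#' `rate`, the two haplotype slots are swapped from that site to the
#' chromosome end — the standard model of a within-chromosome phasing
#' switch error. Rate 0 returns the cohort unchanged.
#'
#' @param cohort a [phased_cohort()].
#' @param rate per-heterozygous-site switch probability in `[0, 1)`.
#' @param samples individuals to perturb (default: all).
#' @return list with the modified `cohort` and `switches`, a data.frame of
#'   the true switch locations (`sample`, `chrom`, `site`: within-chromosome
#'   SNP index at which a switch starts).
#' @export
inject_switch_errors <- function(cohort, rate, samples = cohort$samples) {
  stopifnot(rate >= 0, rate < 1)
  sw <- list()
  if (rate > 0) {
    for (ch in cohort$chromosomes) {
      h <- cohort$haplotypes[[ch]]
      for (id in samples) {
        rows <- hap_rows(cohort, id)
        het <- which(h[rows[1L], ] != h[rows[2L], ])
        if (length(het) == 0L) next
        flips <- runif(length(het)) < rate
        if (!any(flips)) next
        state_h <- cumsum(flips) %% 2L
        state <- c(0L, state_h)[findInterval(seq_len(ncol(h)), het) + 1L]
        swap_cols <- which(state == 1L)
        tmp <- h[rows[1L], swap_cols]
        h[rows[1L], swap_cols] <- h[rows[2L], swap_cols]
        h[rows[2L], swap_cols] <- tmp
        sw[[length(sw) + 1L]] <- data.frame(sample = id, chrom = ch,
                                            site = het[flips],
                                            stringsAsFactors = FALSE)
      }
      cohort$haplotypes[[ch]] <- h
    }
  }
  list(cohort = cohort,
       switches = if (length(sw)) do.call(rbind, sw)
                  else data.frame(sample = character(), chrom = character(),
                                  site = integer(), stringsAsFactors = FALSE))
}
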