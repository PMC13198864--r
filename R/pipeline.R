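#' Pipeline configuration
#'
#' All tunable parameters of the across-chromosome phasing pipeline with
#' their default values: 10 hotspot candidates per chromosome, 25 cM minimum
#' window span, 1/5 per-site dampening exponent, power 2 on the best-match
#' similarity, 0.75 same-chromosome negative-lambda penalty, 0.33
#' relatedness exclusion, MAF >= 0.05 and HWE p > .0005 variant QC.
#'
#' @param hotspots_per_chrom hotspot candidates per chromosome.
#' @param min_span_cM minimum window genetic span.
#' @param psi_exponent per-site dampening exponent of [psi_window()].
#' @param psi_star_power amplification power of [psi_star()].
#' @param same_chrom_penalty negative-lambda penalty of [adjusted_lambda()].
#' @param pihat_max relatedness exclusion threshold.
#' @param maf_min,hwe_p_min variant QC thresholds of [qc_filter()].
#' @param seed optional RNG seed applied by [run_pipeline()].
#' @return A `run_config` list.
#' @export
run_config <- function(hotspots_per_chrom = 10, min_span_cM = 25,
                       psi_exponent = 1 / 5, psi_star_power = 2,
                       same_chrom_penalty = 0.75, pihat_max = 0.33,
                       maf_min = 0.05, hwe_p_min = 0.0005, seed = NULL) {
  structure(list(hotspots_per_chrom = hotspots_per_chrom,
                 min_span_cM = min_span_cM, psi_exponent = psi_exponent,
                 psi_star_power = psi_star_power,
                 same_chrom_penalty = same_chrom_penalty,
                 pihat_max = pihat_max, maf_min = maf_min,
                 hwe_p_min = hwe_p_min, seed = seed),
            class = "run_config")
}

#' Write / read a pipeline configuration
#'
#' YAML round trip for [run_config()]; [run_pipeline()] echoes the effective
#' configuration into its output directory.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` invisibly (write); a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  writeLines(yaml::as.yaml(unclass(config)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::yaml.load_file(path)
  do.call(run_config, vals[!vapply(vals, is.null, logical(1))])
}

#' Phase one focal individual across chromosomes
#'
#' Runs the per-focal core of the method: relatedness exclusion, psi-star
#' tensor construction, and greedy window merging. Pure function of its
#' inputs — focal individuals are independent, so callers may parallelise
#' over them freely with bit-identical per-focal results.
#'
#' @param cohort a QC-filtered [phased_cohort()].
#' @param windows a `window_set` with SNPs assigned.
#' @param focal focal sample id.
#' @param config a [run_config()].
#' @param genotypes optional precomputed [diploid_genotypes()] matrix.
#' @return A `phasing_result` (see [greedy_phase()]) with the tensor
#'   attached as attribute `"tensor"`.
#' @export
phase_focal <- function(cohort, windows, focal, config = run_config(),
                        genotypes = NULL) {
  tensor <- build_psi_star_tensor(cohort, focal, windows,
                                  pihat_max = config$pihat_max,
                                  power = config$psi_star_power,
                                  exponent = config$psi_exponent,
                                  genotypes = genotypes)
  state <- greedy_phase(tensor, penalty = config$same_chrom_penalty)
  attr(state, "tensor") <- tensor
  state
}

#' Run the full across-chromosome phasing pipeline
#'
#' QC-filters the cohort, builds hotspot-delimited windows, phases every
#' requested focal individual, and applies the resulting orientations so
#' that haplotype slot A carries parental set 1 genome-wide. Optionally
#' writes the phased VCF, the window table, per-focal orientations, and the
#' merge logs to a directory.
#'
#' @param cohort a [phased_cohort()], or a path to a phased VCF.
#' @param map a [genetic_map()], or a path to a map file.
#' @param focal character vector of focal sample ids.
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return list with the oriented `cohort`, `windows`, and `results` (named
#'   list of `phasing_result` per focal).
#' @export
run_pipeline <- function(cohort, map, focal, config = run_config(),
                         out_dir = NULL) {
  if (is.character(map)) {
    if (!file.exists(map)) stop("stage map: file not found: ", map)
    map <- read_genetic_map(map)
  }
  if (is.character(cohort)) {
    if (!file.exists(cohort)) stop("stage input: file not found: ", cohort)
    cohort <- read_phased_vcf(cohort, map = map)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  cohort <- tryCatch(
    qc_filter(cohort, config$maf_min, config$hwe_p_min),
    error = function(e) stop("stage qc_filter: ", conditionMessage(e)))
  cohort <- attach_genetic_map(cohort, map)
  windows <- tryCatch(
    make_windows(map, cohort, config$hotspots_per_chrom, config$min_span_cM),
    error = function(e) stop("stage windows: ", conditionMessage(e)))
  genotypes <- pihat_prep(cohort)
  results <- list()
  for (f in focal) {
    results[[f]] <- tryCatch(
      phase_focal(cohort, windows, f, config, genotypes),
      error = function(e) stop("stage phase (focal ", f, "): ",
                               conditionMessage(e)))
    cohort <- apply_orientation(cohort, f, results[[f]])
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_run_config(config, file.path(out_dir, "config.yaml"))
    write_phased_vcf(cohort, file.path(out_dir, "phased.vcf"))
    write_windows(windows, file.path(out_dir, "windows.tsv"))
    ori <- do.call(rbind, lapply(focal, function(f)
      data.frame(focal = f, window = windows$window,
                 chrom = windows$chrom,
                 orientation = results[[f]]$orientation,
                 uninformative = results[[f]]$uninformative,
                 stringsAsFactors = FALSE)))
    write.table(ori, file.path(out_dir, "orientations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    logs <- do.call(rbind, lapply(focal, function(f)
      cbind(focal = f, results[[f]]$merge_log)))
    write.table(logs, file.path(out_dir, "merges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(cohort = cohort, windows = windows, results = results)
}

#' QC-filter a simulated cohort coherently
#'
#' Applies the [qc_filter()] criteria to a [simulate_cohort()] result while
#' keeping the parental genotype vectors and exact-truth variant indices
#' aligned with the filtered variant set.
#'
#' @param sim a `sim_cohort`.
#' @param maf_min,hwe_p_min see [qc_filter()].
#' @return The `sim_cohort` with `cohort`, `parents`, and `truth` filtered
#'   and re-indexed.
#' @export
qc_filter_sim <- function(sim, maf_min = 0.05, hwe_p_min = 0.0005) {
  cohort <- compute_allele_frequencies(sim$cohort, recode = FALSE)
  keep <- cohort$variants$maf >= maf_min
  hwe_p <- hwe_pvalues(cohort)
  keep <- keep & !is.na(hwe_p) & hwe_p > hwe_p_min
  new_row <- cumsum(keep)
  sim$cohort <- subset_variants(cohort, keep)
  sim$parents <- lapply(sim$parents, function(p)
    list(p1 = p$p1[keep], p2 = p$p2[keep]))
  sim$truth <- lapply(sim$truth, function(tr) {
    ok <- keep[tr$calls$row]
    tr$calls <- tr$calls[ok, , drop = FALSE]
    tr$calls$row <- new_row[tr$calls$row]
    rownames(tr$calls) <- NULL
    tr
  })
  sim
}

#' Trio-based evaluation of an across-chromosome phased cohort
#'
#' For each pedigree row whose offspring is in the phased cohort and whose
#' parents are in the parent cohort, derives trio truth
#' ([trio_ground_truth()]) and scores the phasing ([acpa()]).
#'
#' @param phased a phased [phased_cohort()] (focal slot A = parental set 1).
#' @param parents_cohort a [phased_cohort()] holding parental genotypes on
#'   the same variant set (chromosome/position are validated).
#' @param ped data.frame with columns `child`, `father`, `mother` (PED-style;
#'   extra columns ignored).
#' @return list of `acpa_report`, named by child id.
#' @export
eval_trios <- function(phased, parents_cohort, ped) {
  if (!identical(phased$variants$pos, parents_cohort$variants$pos) ||
      !identical(phased$variants$chrom, parents_cohort$variants$chrom))
    stop("phased and parent cohorts must share the same variant set")
  g_par <- diploid_genotypes(parents_cohort)
  out <- list()
  for (k in seq_len(nrow(ped))) {
    child <- ped$child[k]
    if (!child %in% phased$samples) next
    truth <- trio_ground_truth(phased, child,
                               g_par[ped$father[k], ], g_par[ped$mother[k], ])
    out[[child]] <- acpa(phased, truth)
  }
  out
}
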