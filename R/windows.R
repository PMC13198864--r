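#' Recombination hotspot candidates for one chromosome
#'
#' Ranks the intervals between consecutive genetic-map anchors by their
#' recombination intensity — the ratio of genetic distance (cM) to physical
#' distance (Mb) — and returns the midpoints (bp) of the `k` hottest
#' intervals as candidate window boundaries, sorted by position. Ties in the
#' ratio are broken in favour of the smaller bp position.
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome label.
#' @param k number of hotspots to return (all intervals, with a warning, if
#'   the map has fewer than `k`).
#' @return numeric vector of boundary positions (bp), sorted.
#' @export
hotspot_candidates <- function(map, chrom, k = 10) {
  s <- map[map$chrom == chrom, ]
  if (nrow(s) < 2L) stop("no map intervals on chromosome ", chrom)
  d_cM <- diff(s$cM)
  d_Mb <- diff(s$pos) / 1e6
  ratio <- d_cM / d_Mb
  n_int <- length(ratio)
  if (n_int < k) {
    warning("chromosome ", chrom, " has only ", n_int,
            " map intervals (< k = ", k, "); returning all")
    k <- n_int
  }
  ord <- order(-ratio, s$pos[-nrow(s)])     # ratio desc, then smaller bp
  top <- sort(ord[seq_len(k)])
  mid <- (s$pos[top] + s$pos[top + 1L]) / 2
  sort(mid)
}

#' Build hotspot-delimited windows for one chromosome
#'
#' Sweeps the sorted candidate boundaries left to right; a candidate becomes
#' a window boundary iff the window it would close spans at least
#' `min_span_cM` of genetic distance. The final window extends to the
#' chromosome end and is merged into its left neighbour if it falls short of
#' `min_span_cM`. A chromosome genetically shorter than `min_span_cM` yields
#' a single whole-chromosome window.
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome label.
#' @param candidates sorted candidate boundary positions (bp), e.g. from
#'   [hotspot_candidates()].
#' @param min_span_cM minimum genetic span per window (cM).
#' @return data.frame of windows: `chrom`, `start_bp`, `end_bp` (half-open),
#'   `start_cM`, `end_cM`, `span_cM`.
#' @export
build_windows <- function(map, chrom, candidates, min_span_cM = 25) {
  s <- map[map$chrom == chrom, ]
  chrom_start <- s$pos[1L]
  chrom_end <- s$pos[nrow(s)] + 1          # half-open: include last bp
  cm_at <- function(bp) interpolate_genetic_position(map, chrom, bp)
  total_cM <- s$cM[nrow(s)] - s$cM[1L]
  boundaries <- numeric(0)
  prev_cM <- s$cM[1L]
  for (b in sort(candidates)) {
    if (b <= chrom_start || b >= chrom_end) next
    if (cm_at(b) - prev_cM >= min_span_cM) {
      boundaries <- c(boundaries, b)
      prev_cM <- cm_at(b)
    }
  }
  # terminal window: merge into left neighbour if too short
  if (length(boundaries) > 0 &&
      s$cM[nrow(s)] - cm_at(boundaries[length(boundaries)]) < min_span_cM)
    boundaries <- boundaries[-length(boundaries)]
  if (total_cM < min_span_cM)
    message("chromosome ", chrom, " spans only ", round(total_cM, 2),
            " cM (< ", min_span_cM, "); single whole-chromosome window")
  starts <- c(chrom_start, boundaries)
  ends <- c(boundaries, chrom_end)
  data.frame(
    chrom = chrom, start_bp = starts, end_bp = ends,
    start_cM = cm_at(starts), end_cM = cm_at(ends),
    span_cM = cm_at(ends) - cm_at(starts),
    stringsAsFactors = FALSE
  )
}

#' Build the genome-wide window set
#'
#' Runs [hotspot_candidates()] and [build_windows()] on every chromosome of
#' the map and, if a cohort is given, assigns SNPs to windows
#' ([assign_snps()]).
#'
#' @param map a [genetic_map()].
#' @param cohort optional [phased_cohort()] whose SNPs are assigned.
#' @param hotspots_per_chrom number of hotspot candidates per chromosome.
#' @param min_span_cM minimum genetic span per window (cM).
#' @return A `window_set`: data.frame with one row per window (`chrom`,
#'   `window` global index, spans, and after assignment `snp_start`,
#'   `snp_end` global variant row range and `n_snps`).
#' @export
make_windows <- function(map, cohort = NULL, hotspots_per_chrom = 10,
                         min_span_cM = 25) {
  chroms <- unique(map$chrom)
  ws <- do.call(rbind, lapply(chroms, function(ch)
    build_windows(map, ch, hotspot_candidates(map, ch, hotspots_per_chrom),
                  min_span_cM)))
  ws$window <- seq_len(nrow(ws))
  class(ws) <- c("window_set", "data.frame")
  if (!is.null(cohort)) ws <- assign_snps(ws, cohort)
  ws
}

#' Assign cohort SNPs to windows
#'
#' Each SNP joins the window whose half-open bp span `[start_bp, end_bp)`
#' contains it (a SNP exactly on a boundary goes to the right window). SNPs
#' outside all spans are assigned to the nearest terminal window with a
#' message. Windows left empty are dropped with a warning and their span
#' folded into a neighbour.
#'
#' @param windows a `window_set` from [make_windows()]/[build_windows()].
#' @param cohort a [phased_cohort()].
#' @return The window set with `snp_start`/`snp_end` (global variant row
#'   indices, inclusive) and `n_snps` filled; window indices renumbered if
#'   any empty window was dropped.
#' @export
assign_snps <- function(windows, cohort) {
  windows$snp_start <- NA_integer_
  windows$snp_end <- NA_integer_
  windows$n_snps <- 0L
  drop <- logical(nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    rows <- which(cohort$variants$chrom == ch)
    if (length(rows) == 0L) { drop[wi] <- TRUE; next }
    pos <- cohort$variants$pos[rows]
    idx <- findInterval(pos, windows$start_bp[wi])
    if (any(idx == 0L)) {
      message("assign_snps: ", sum(idx == 0L), " SNP(s) before first window on ",
              ch, " assigned to it")
      idx[idx == 0L] <- 1L
    }
    beyond <- pos >= windows$end_bp[wi[length(wi)]]
    if (any(beyond)) {
      message("assign_snps: ", sum(beyond), " SNP(s) beyond last window on ",
              ch, " assigned to it")
      idx[beyond] <- length(wi)
    }
    for (j in seq_along(wi)) {
      in_w <- which(idx == j)
      if (length(in_w) == 0L) { drop[wi[j]] <- TRUE; next }
      windows$snp_start[wi[j]] <- rows[min(in_w)]
      windows$snp_end[wi[j]] <- rows[max(in_w)]
      windows$n_snps[wi[j]] <- length(in_w)
    }
    # fold spans of empty windows into their left (or right) neighbour
    for (j in which(drop[wi])) {
      if (j > 1L) {
        windows$end_bp[wi[j - 1L]] <- windows$end_bp[wi[j]]
        windows$end_cM[wi[j - 1L]] <- windows$end_cM[wi[j]]
      } else if (length(wi) > 1L) {
        windows$start_bp[wi[2L]] <- windows$start_bp[wi[1L]]
        windows$start_cM[wi[2L]] <- windows$start_cM[wi[1L]]
      }
    }
  }
  if (any(drop)) {
    warning("assign_snps: dropped ", sum(drop),
            " empty window(s); spans folded into neighbours")
    windows <- windows[!drop, , drop = FALSE]
  }
  windows$span_cM <- windows$end_cM - windows$start_cM
  windows$window <- seq_len(nrow(windows))
  rownames(windows) <- NULL
  class(windows) <- c("window_set", "data.frame")
  windows
}

#' Write / read a window table
#'
#' @param windows a `window_set`.
#' @param path TSV file path.
#' @return `path` invisibly (write); a `window_set` (read).
#' @export
write_windows <- function(windows, path) {
  write.table(as.data.frame(windows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  ws <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  ws$chrom <- as.character(ws$chrom)
  class(ws) <- c("window_set", "data.frame")
  ws
}
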